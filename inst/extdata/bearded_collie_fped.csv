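dog_id,all_possible_generations,unique_ancestors,fped_all,fped_10gen,fped_5gen
BC1570,23,192,0.31,0.31,0.13
BC1696,26,247,0.29,0.28,0.09
BC1838,26,256,0.31,0.30,0.11
BC1852,27,344,0.32,0.27,0.13
BC1893,28,399,0.27,0.23,0.06
BC1894,28,289,0.27,0.25,0.05
BC1895,26,270,0.26,0.24,0.05
BC1896,23,192,0.31,0.31,0.13
BC1899,25,289,0.25,0.24,0.04
BC1901,30,504,0.29,0.23,0.01
BC1904,24,196,0.33,0.33,0.07
BC1905,27,368,0.26,0.22,0.05
BC1909,29,425,0.32,0.23,0.04
BC1911,27,331,0.28,0.23,0.01
BC1916,27,405,0.25,0.23,0.01
BC1918,27,270,0.34,0.29,0.11
BC1936,26,396,0.27,0.26,0.07
BC1943,23,266,0.21,0.21,0.03
BC1944,25,219,0.29,0.28,0.11
BC1945,28,317,0.29,0.27,0.07
BC1952,30,557,0.27,0.15,0.01
BC0057,27,253,0.41,0.39,0.22
BC0058,29,502,0.28,0.17,0.05
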