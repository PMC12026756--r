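dog_id,fped_all,froh_snp,froh_wgs
BC1570,0.31,0.37,0.27
BC1696,0.29,0.39,0.35
BC1838,0.31,0.35,0.34
BC1852,0.32,0.37,0.36
BC1893,0.27,0.43,0.40
BC1894,0.27,0.32,0.24
BC1895,0.26,0.34,0.33
BC1896,0.31,0.38,0.36
BC1899,0.25,0.28,0.18
BC1901,0.29,0.31,0.30
BC1904,0.33,0.44,0.39
BC1905,0.26,0.31,0.28
BC1909,0.32,0.31,0.29
BC1911,0.28,0.32,0.30
BC1916,0.25,0.35,0.33
BC1918,0.34,0.45,0.40
BC1936,0.27,0.34,0.33
BC1943,0.21,0.24,0.22
BC1944,0.29,0.31,0.29
BC1945,0.29,0.36,0.34
BC1952,0.27,0.38,0.37
BC0057,0.41,0.46,0.43
BC0058,0.28,0.35,0.35
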