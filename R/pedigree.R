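#' Build a pedigree table
#'
#' Normalizes a data frame of parent records into the pedigree container
#' used by the inbreeding routines. Unknown-parent codes `"0"`, `""`,
#' `"NA"` and `NA` are all accepted and stored as `NA`.
#'
#' @param x data.frame with columns `id`, `sire`, `dam` and optionally
#'   `year`.
#' @return A `data.frame` of class `pedigree` with character `id`, `sire`,
#'   `dam` (NA = unknown) and integer `year`.
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x))) stop("pedigree needs columns id, sire, dam")
  clean <- function(v) {
    v <- trimws(as.character(v))
    v[v %in% c("0", "", "NA")] <- NA_character_
    v
  }
  ped <- data.frame(
    id = trimws(as.character(x$id)),
    sire = clean(x$sire),
    dam = clean(x$dam),
    year = if ("year" %in% names(x)) as.integer(x$year) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Integer parent arrays (0 = unknown); parents referenced but not listed are
# treated as unknown founders.
ped_index <- function(ped) {
  idx <- function(p) {
    m <- match(p, ped$id)
    m[is.na(p)] <- NA_integer_
    ifelse(is.na(m), 0L, m)
  }
  list(id = ped$id, sire = idx(ped$sire), dam = idx(ped$dam))
}

# Topological order (parents before offspring); errors on cycles with the
# offending path.
ped_topo_order <- function(px) {
  n <- length(px$id)
  state <- integer(n)          # 0 unvisited, 1 on stack, 2 done
  order_out <- integer(0)
  path <- character(0)
  visit <- function(i) {
    if (state[i] == 2L) return(invisible())
    if (state[i] == 1L) {
      stop("pedigree contains a cycle through: ",
           paste(c(path[seq(match(px$id[i], path), length(path))], px$id[i]),
                 collapse = " -> "))
    }
    state[i] <<- 1L
    path <<- c(path, px$id[i])
    for (p in c(px$sire[i], px$dam[i])) if (p > 0L) visit(p)
    path <<- path[-length(path)]
    state[i] <<- 2L
    order_out <<- c(order_out, i)
  }
  for (i in seq_len(n)) visit(i)
  order_out
}

# Memoized kinship on indexed pedigree. topo_rank[i] gives topological rank
# so that recursion always expands the later (younger) individual.
make_kinship <- function(px) {
  topo <- ped_topo_order(px)
  rank <- integer(length(topo))
  rank[topo] <- seq_along(topo)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (rank[a] > rank[b]) { tmp <- a; a <- b; b <- tmp }
    key <- paste0(a, ":", b)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (a == b) {
      0.5 * (1 + phi(px$sire[a], px$dam[a]))
    } else {
      0.5 * (phi(a, px$sire[b]) + phi(a, px$dam[b]))
    }
    memo[[key]] <- v
    v
  }
  phi
}

# Minimum generation distance from focal to every individual following
# parent links (0 = focal, Inf = not an ancestor).
ancestor_distances <- function(px, focal_i) {
  n <- length(px$id)
  dist <- rep(Inf, n)
  dist[focal_i] <- 0
  frontier <- focal_i
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    parents <- unique(c(px$sire[frontier], px$dam[frontier]))
    parents <- parents[parents > 0L]
    parents <- parents[dist[parents] > d]
    dist[parents] <- d
    frontier <- parents
  }
  dist
}

#' Truncate a pedigree at a generation depth
#'
#' Restricts the ancestry of `focal` to the most recent `depth` generations:
#' ancestors whose minimum parent-path distance from the focal individual
#' exceeds `depth` are dropped, and ancestors at distance exactly `depth`
#' keep their id but lose their parents (they become founders). An ancestor
#' reachable at several distances is kept whenever its shortest path is
#' within `depth`. `depth = Inf` returns the pedigree unchanged.
#'
#' @param ped a `pedigree`.
#' @param focal focal individual id.
#' @param depth generations to retain (>= 1, or `Inf`).
#' @return a truncated `pedigree`.
#' @export
truncate_pedigree <- function(ped, focal, depth = Inf) {
  focal_i <- match(focal, ped$id)
  if (is.na(focal_i)) stop("unknown focal id: ", focal)
  if (is.infinite(depth)) return(ped)
  if (depth < 1) stop("depth must be >= 1 or Inf")
  px <- ped_index(ped)
  dist <- ancestor_distances(px, focal_i)
  keep <- is.infinite(dist) | dist <= depth
  out <- ped[keep, , drop = FALSE]
  kept_ids <- out$id
  at_edge <- dist[keep] == depth
  out$sire[at_edge | !(out$sire %in% kept_ids)] <- NA_character_
  out$dam[at_edge | !(out$dam %in% kept_ids)] <- NA_character_
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Wright's inbreeding coefficient at a generation depth
#'
#' F is the kinship of the focal individual's parents on the pedigree
#' truncated to `depth` generations, computed with the standard recursive
#' kinship: phi(a, a) = (1 + F_a)/2 and
#' phi(a, b) = (phi(a, sire_b) + phi(a, dam_b))/2, unknown parents
#' contributing zero. This equals Wright's path-counting sum
#' sum (1/2)^(n1+n2+1) (1 + F_A) over common ancestors A.
#'
#' @param ped a `pedigree`.
#' @param focal focal individual id.
#' @param depth generations of ancestry to use (default all).
#' @return A one-row data.frame: `id`, `fped`, `depth`,
#'   `unique_ancestors` (distinct ancestors within `depth`),
#'   `max_depth` (longest ancestor path within `depth`).
#' @export
f_ped <- function(ped, focal, depth = Inf) {
  tped <- truncate_pedigree(ped, focal, depth)
  px <- ped_index(tped)
  focal_i <- match(focal, tped$id)
  phi <- make_kinship(px)
  f <- phi(px$sire[focal_i], px$dam[focal_i])
  s <- pedigree_summaries(tped, focal)
  data.frame(id = focal, fped = f, depth = depth,
             unique_ancestors = s$unique_ancestors,
             max_depth = s$max_depth, stringsAsFactors = FALSE)
}

#' Pedigree summaries for one individual
#'
#' @param ped a `pedigree`.
#' @param focal focal individual id.
#' @param depth generations to consider (default all).
#' @return list with `unique_ancestors` (cardinality of the ancestor set,
#'   focal excluded, within `depth`) and `max_depth` (length of the longest
#'   parent-link path from the focal individual).
#' @export
pedigree_summaries <- function(ped, focal, depth = Inf) {
  tped <- truncate_pedigree(ped, focal, depth)
  px <- ped_index(tped)
  focal_i <- match(focal, tped$id)
  dist <- ancestor_distances(px, focal_i)
  n_anc <- sum(is.finite(dist)) - 1L
  # longest path: memoized depth over parent links
  maxd <- rep(NA_real_, length(px$id))
  longest <- function(i) {
    if (i == 0L) return(0)
    if (!is.na(maxd[i])) return(maxd[i])
    v <- if (px$sire[i] == 0L && px$dam[i] == 0L) 0 else
      1 + max(longest(px$sire[i]), longest(px$dam[i]))
    maxd[i] <<- v
    v
  }
  list(unique_ancestors = n_anc, max_depth = as.integer(longest(focal_i)))
}

#' Inbreeding coefficients for a cohort at several depths
#'
#' Computes F for each requested individual at each generation depth and
#' summarizes the cohort with mean and sample SD (n - 1) per depth, rounded
#' to 2 decimals in the summary.
#'
#' @param ped a `pedigree`.
#' @param ids individual ids (must exist in `ped`).
#' @param depths numeric vector of depths (`Inf` = all generations).
#' @return list with `individuals` (one row per id x depth) and `summary`
#'   (per-depth mean/sd over the cohort).
#' @export
cohort_fped_table <- function(ped, ids, depths = c(5, 10, Inf)) {
  if (length(ids) == 0) stop("empty id list")
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids)) stop("unknown ids: ", paste(missing_ids, collapse = ", "))
  rows <- do.call(rbind, lapply(depths, function(g) {
    do.call(rbind, lapply(ids, function(i) f_ped(ped, i, g)))
  }))
  summ <- do.call(rbind, lapply(depths, function(g) {
    v <- rows$fped[rows$depth == g]
    data.frame(depth = g, mean = round(mean(v), 2), sd = round(sd(v), 2),
               n = length(v))
  }))
  list(individuals = rows, summary = summ)
}

#' Mean and sample SD of a printed table column
#'
#' Convenience summary used to reproduce cohort averages from per-individual
#' values: mean and sample SD (n - 1) rounded to the requested number of
#' decimals, the convention used in breed-diversity reports.
#'
#' @param x numeric vector.
#' @param digits decimals to round to (default 2).
#' @return list with `mean` and `sd`.
#' @export
cohort_mean_sd <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  list(mean = round(mean(x), digits), sd = round(sd(x), digits))
}
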