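#' Read a gene-set collection from GMT
#'
#' @param path GMT file (tab-separated: name, description, members).
#' @return Named list of identifier vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= k)` of observing `k = |query intersect set|` successes when
#' drawing `n = |query|` identifiers from a universe of size `N`
#' containing `K = |set|` members. One-sided (over-representation
#' only); BH adjustment across sets; rows sorted by adjusted p. Query
#' identifiers outside the universe are dropped with a logged count,
#' and sets are intersected with the universe.
#'
#' @param query Differential identifier set.
#' @param sets Named list of identifier vectors (e.g. [read_gmt()]).
#' @param universe Background identifiers (e.g. all quantified
#'   proteins).
#' @return Data frame: `term`, `k`, `set_size`, `query_size`,
#'   `universe_size`, `p.value`, `adj.p.value`, `percent_members`;
#'   attribute `"dropped"` counts query ids outside the universe.
#' @export
ora_hypergeometric <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query0 <- unique(query)
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  if (dropped > 0) {
    message(dropped, " query identifier(s) outside the universe dropped")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(term = nm, k = k, set_size = K, query_size = n,
               universe_size = N, p.value = p,
               percent_members = percent_members(query, set),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj.p.value <- bh_adjust(out$p.value)
  out <- out[order(out$adj.p.value, out$p.value),
             c("term", "k", "set_size", "query_size", "universe_size",
               "p.value", "adj.p.value", "percent_members")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Percentage of the dysregulated set found in a term
#'
#' `100 * |query intersect term| / |query|` — the "% Members" statistic
#' used to size enrichment dot plots: the percentage of the
#' differential proteins that belong to the given ontology term.
#'
#' @param query Non-empty differential identifier set.
#' @param term_set Term identifiers.
#' @return Percentage in [0, 100].
#' @export
percent_members <- function(query, term_set) {
  query <- unique(query)
  if (!length(query)) stop("empty query set")
  100 * length(intersect(query, unique(term_set))) / length(query)
}

#' Cross-tissue overlap of differential proteins
#'
#' Counts, for every protein differential in any tissue, the number of
#' tissues in which it is differential, and summarises how many
#' proteins are shared by at least 2, 3, ... up to all tissues.
#' Invariant to the order tissues are supplied.
#'
#' @param de_sets Named list (>= 2) of per-tissue differential
#'   identifier sets.
#' @return List with `counts` (data frame `protein`, `n_tissues`,
#'   plus one logical membership column per tissue), `summary`
#'   (`union`, and `ge2`, `ge3`, ... counts), and `members` (list of
#'   proteins at each >= k threshold).
#' @export
cross_tissue_overlap <- function(de_sets) {
  if (length(de_sets) < 2) stop("need >= 2 tissue sets")
  if (is.null(names(de_sets))) {
    names(de_sets) <- paste0("tissue", seq_along(de_sets))
  }
  de_sets <- lapply(de_sets, unique)
  proteins <- sort(unique(unlist(de_sets)))
  member <- vapply(de_sets, function(s) proteins %in% s,
                   logical(length(proteins)))
  if (length(proteins) == 1L) member <- matrix(member, nrow = 1,
    dimnames = list(NULL, names(de_sets)))
  n_tissues <- rowSums(member)
  counts <- data.frame(protein = proteins, n_tissues = n_tissues,
                       member, stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_tissues, counts$protein), ]
  rownames(counts) <- NULL
  ks <- 2:length(de_sets)
  summary <- c(union = length(proteins),
               stats::setNames(vapply(ks, function(k) sum(n_tissues >= k),
                                      integer(1)),
                               paste0("ge", ks)))
  members <- stats::setNames(
    lapply(ks, function(k) counts$protein[counts$n_tissues >= k]),
    paste0("ge", ks))
  list(counts = counts, summary = summary, members = members)
}
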