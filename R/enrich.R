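# Weighted pre-ranked gene-set enrichment with a gene-tag permutation
# null, sign-stratified FDR, leading-edge candidate ranking, overlap
# analysis, and hypergeometric over-representation.

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list in rank order: at a member of the set ("hit") the
#' running sum increases by `|mean_r|^p / N_R` (`N_R` the sum of
#' `|mean_r|^p` over hits), at a non-member it decreases by
#' `1 / (N - N_H)`. The enrichment score (ES) is the signed
#' maximum-magnitude deviation from zero; with `p = 0` this reduces to a
#' Kolmogorov-Smirnov statistic between the hit and miss rank
#' distributions. The running sum is evaluated in closed form at its
#' breakpoints (values change direction only at hits), so the cost is
#' linear in the set size rather than the list length.
#'
#' @param ranked ranked list data frame with `gene_id` and `mean_r` in rank
#'   order (see [rank_list()]).
#' @param members character vector of set member gene ids; members outside
#'   the list universe are ignored.
#' @param p weight exponent (1 = weighted, 0 = classic).
#' @param profile if `TRUE`, also return the full running-sum curve.
#' @return list with `es`, `peak_rank` (rank at which the extreme
#'   deviation is attained), `leading_edge` (gene ids), `n_hits`, `n_r`,
#'   and optionally `running`.
#' @export
enrichment_score <- function(ranked, members, p = 1, profile = FALSE) {
  N <- nrow(ranked)
  hits <- sort(match(unique(members), ranked$gene_id))
  hits <- hits[!is.na(hits)]
  k <- length(hits)
  if (k < 1L) stop("gene set has no members in the ranked universe")
  if (k >= N) stop("gene set covers the whole ranked universe")
  w <- abs(ranked$mean_r[hits])^p
  n_r <- sum(w)
  if (n_r == 0) stop("degenerate weights")
  miss <- 1 / (N - k)
  cw <- cumsum(w) / n_r
  jj <- seq_len(k)
  after <- cw - (hits - jj) * miss          # value of the curve at rank hits[j]
  before <- c(0, cw[-k]) - (hits - jj) * miss # value at rank hits[j] - 1
  cand <- c(after, before)
  cand_rank <- c(hits, hits - 1L)
  best <- pick_extreme(cand)
  es <- cand[best]
  peak_rank <- cand_rank[best]
  if (es > 0) {
    le <- ranked$gene_id[hits[hits <= peak_rank]]
  } else if (es < 0) {
    le <- ranked$gene_id[hits[hits >= peak_rank]]
  } else {
    le <- character(0)
  }
  out <- list(es = es, peak_rank = peak_rank, leading_edge = le,
              n_hits = k, n_r = n_r)
  if (profile) {
    steps <- rep(-miss, N)
    steps[hits] <- w / n_r
    out$running <- cumsum(steps)
  }
  out
}

# ES only, from precomputed |stat|^p weights over the whole list; used for
# permutations. hits must be sorted, weights w_all aligned with rank order.
es_value <- function(w_all, hits, N) {
  k <- length(hits)
  w <- w_all[hits]
  n_r <- sum(w)
  if (n_r == 0) return(0)
  miss <- 1 / (N - k)
  jj <- seq_len(k)
  cw <- cumsum(w) / n_r
  after <- cw - (hits - jj) * miss
  before <- c(0, cw[-k]) - (hits - jj) * miss
  cand <- c(after, before)
  cand[pick_extreme(cand)]
}

# index of the signed maximum-magnitude deviation; when the positive and
# negative extremes tie in magnitude (to within numerical noise), the
# positive one wins, so the tie-break is stable under reordering of the
# floating-point sums
pick_extreme <- function(cand) {
  m <- max(abs(cand))
  near <- which(abs(cand) >= m - 1e-12)
  near[which.max(cand[near])]
}

#' Gene-tag permutation null for a set size
#'
#' Draws `n_perm` random gene sets of the given size without replacement
#' from the ranked universe and returns their enrichment scores. This is
#' the pre-ranked null: with no phenotype labels to permute, significance
#' is assessed against random same-size tags.
#'
#' @param ranked ranked list data frame.
#' @param set_size number of genes per null set (< universe size).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param p weight exponent.
#' @return numeric vector of `n_perm` null ES values.
#' @export
permutation_null <- function(ranked, set_size, n_perm, seed = 1, p = 1) {
  N <- nrow(ranked)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (set_size >= N) stop("set_size must be smaller than the universe")
  set.seed(seed)
  w_all <- abs(ranked$mean_r)^p
  vapply(seq_len(n_perm),
         function(i) es_value(w_all, sort(sample.int(N, set_size)), N),
         numeric(1))
}

#' Normalize enrichment scores and compute sign-stratified FDR
#'
#' NES divides each ES by the mean magnitude of same-signed null ES for
#' that set (null ES are normalized the same way). The nominal p value is
#' the fraction of same-signed null ES at least as extreme; when no null ES
#' shares the sign, the floor `1 / (n_perm + 1)` is used and flagged. The
#' FDR q of a set is the ratio of the fraction of pooled same-signed null
#' NES at least as extreme as its NES to the fraction of observed
#' same-signed NES at least as extreme, capped at 1.
#'
#' @param results data frame with `set_id` and `es` (one row per set).
#' @param nulls named list of null ES vectors, one per set (from
#'   [permutation_null()], any shared cache is fine as long as sizes
#'   match).
#' @return `results` with added columns `nes`, `nominal_p`, `fdr_q`,
#'   `p_floor` (logical flag).
#' @export
normalize_and_fdr <- function(results, nulls) {
  stopifnot(all(results$set_id %in% names(nulls)))
  n <- nrow(results)
  nes <- numeric(n)
  nominal_p <- numeric(n)
  p_floor <- logical(n)
  null_nes <- vector("list", n)
  for (i in seq_len(n)) {
    es <- results$es[i]
    nv <- nulls[[results$set_id[i]]]
    pos_mean <- mean(nv[nv > 0])
    neg_mean <- mean(abs(nv[nv < 0]))
    nn <- numeric(length(nv))
    if (is.finite(pos_mean) && pos_mean > 0) nn[nv > 0] <- nv[nv > 0] / pos_mean
    if (is.finite(neg_mean) && neg_mean > 0) nn[nv < 0] <- nv[nv < 0] / neg_mean
    null_nes[[i]] <- nn
    if (es > 0) {
      same <- nv[nv > 0]
      nes[i] <- if (length(same) > 0) es / pos_mean else NA_real_
      if (length(same) == 0) {
        nominal_p[i] <- 1 / (length(nv) + 1)
        p_floor[i] <- TRUE
      } else nominal_p[i] <- mean(same >= es)
    } else if (es < 0) {
      same <- nv[nv < 0]
      nes[i] <- if (length(same) > 0) es / neg_mean else NA_real_
      if (length(same) == 0) {
        nominal_p[i] <- 1 / (length(nv) + 1)
        p_floor[i] <- TRUE
      } else nominal_p[i] <- mean(same <= es)
    } else {
      nes[i] <- 0
      nominal_p[i] <- 1
    }
  }
  pool <- unlist(null_nes)
  pool_pos <- pool[pool > 0]
  pool_neg <- pool[pool < 0]
  obs_pos <- nes[!is.na(nes) & nes > 0]
  obs_neg <- nes[!is.na(nes) & nes < 0]
  fdr_q <- rep(1, n)
  for (i in seq_len(n)) {
    if (is.na(nes[i]) || nes[i] == 0) next
    if (nes[i] > 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes[i]) else 0
      den <- mean(obs_pos >= nes[i])
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes[i]) else 0
      den <- mean(obs_neg <= nes[i])
    }
    fdr_q[i] <- min(1, num / den)
  }
  results$nes <- nes
  results$nominal_p <- nominal_p
  results$fdr_q <- fdr_q
  results$p_floor <- p_floor
  results
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Runs the full weighted pre-ranked procedure for a gene-set library:
#' size filtering after intersection with the ranked universe, enrichment
#' scores, gene-tag permutation null (cached per set size), normalization,
#' nominal p values, sign-stratified FDR, and leading-edge subsets.
#'
#' @param ranked ranked list data frame (see [rank_list()]).
#' @param gene_sets named list of member gene-id vectors.
#' @param p weight exponent (default 1, the weighted statistic).
#' @param n_perm permutations per set size (default 1000).
#' @param seed RNG seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   universe.
#' @return data frame of class `enrichment_result`: `set_id`, `size`,
#'   `es`, `nes`, `nominal_p`, `fdr_q`, `sign`, `peak_rank`,
#'   `leading_edge` (list column). Attribute `skipped` lists sets outside
#'   the size bounds.
#' @export
gsea_preranked <- function(ranked, gene_sets, p = 1, n_perm = 1000, seed = 1,
                           min_size = 15, max_size = 500) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  universe <- ranked$gene_id
  trimmed <- lapply(gene_sets, function(g) intersect(unique(g), universe))
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(gene_sets)[!keep]
  trimmed <- trimmed[keep]
  sizes <- sizes[keep]
  if (length(trimmed) == 0L) stop("no gene sets within the size bounds")

  scores <- lapply(trimmed, function(g) enrichment_score(ranked, g, p = p))
  results <- data.frame(
    set_id = names(trimmed),
    size = as.integer(sizes),
    es = vapply(scores, `[[`, numeric(1), "es"),
    peak_rank = vapply(scores, function(s) as.numeric(s$peak_rank), numeric(1)),
    stringsAsFactors = FALSE
  )

  # one null sample per distinct set size, reused by all sets of that size
  cache <- new.env(parent = emptyenv())
  nulls <- lapply(seq_along(trimmed), function(i) {
    key <- as.character(sizes[i])
    if (is.null(cache[[key]]))
      cache[[key]] <- permutation_null(ranked, sizes[i], n_perm,
                                       seed = child_seed(seed, sizes[i]), p = p)
    cache[[key]]
  })
  names(nulls) <- results$set_id
  results <- normalize_and_fdr(results, nulls)
  results$sign <- sign(results$es)
  results$leading_edge <- I(lapply(scores, `[[`, "leading_edge"))
  attr(results, "skipped") <- skipped
  class(results) <- c("enrichment_result", class(results))
  results
}

#' Significantly enriched sets of one sign
#'
#' @param results an `enrichment_result` data frame.
#' @param sign `+1` or `-1`.
#' @param fdr FDR threshold.
#' @return the subset of rows; possibly empty (a valid outcome).
#' @export
significant_sets <- function(results, sign, fdr = 0.05) {
  results[!is.na(results$fdr_q) & results$fdr_q < fdr &
            results$sign == sign, , drop = FALSE]
}

#' Leading-edge candidate gene ranking
#'
#' Counts, for each gene, the number of significant same-sign sets in whose
#' leading edge it appears, then ranks by that count (descending), breaking
#' ties by mean correlation magnitude (most extreme first) and then by gene
#' id, truncating to `top_n`. With no significant set of a sign, no
#' candidate list is produced for that sign.
#'
#' @param results an `enrichment_result` data frame.
#' @param ranked the ranked list the results came from.
#' @param fdr FDR threshold defining significance.
#' @param top_n list length (default 10).
#' @return list with elements `positive` and `negative`, each `NULL` or a
#'   data frame `gene_id`, `n_leading_edge_sets`, `mean_r`.
#' @export
candidate_ranking <- function(results, ranked, fdr = 0.05, top_n = 10) {
  one_sign <- function(s) {
    sig <- significant_sets(results, s, fdr)
    if (nrow(sig) == 0L) return(NULL)
    tab <- table(unlist(sig$leading_edge))
    df <- data.frame(gene_id = names(tab),
                     n_leading_edge_sets = as.integer(tab),
                     stringsAsFactors = FALSE)
    df$mean_r <- ranked$mean_r[match(df$gene_id, ranked$gene_id)]
    df <- df[order(-df$n_leading_edge_sets, -abs(df$mean_r), df$gene_id), ]
    rownames(df) <- NULL
    utils::head(df, top_n)
  }
  list(positive = one_sign(1), negative = one_sign(-1))
}

#' Overlap between two compartments' signatures
#'
#' Intersections and set differences of the significant gene sets and of
#' their member-gene unions, with percentages computed as
#' `100 * shared / union` and reported half-up to one decimal. When a
#' gene-set library and universe are supplied, each gene partition (shared,
#' only-A, only-B) is additionally tested for over-representation.
#'
#' @param genes_a,genes_b character vectors: member-gene unions of the
#'   significant sets per compartment.
#' @param sets_a,sets_b character vectors of significant set ids per
#'   compartment.
#' @param gene_sets optional named list for [ora()].
#' @param universe optional gene universe for [ora()].
#' @return list with `sets` and `genes` summaries (shared/only counts,
#'   union, `pct_shared`), the partition gene lists, and optional `ora`
#'   results per partition.
#' @export
overlap_analysis <- function(genes_a, genes_b, sets_a, sets_b,
                             gene_sets = NULL, universe = NULL) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  sets_a <- unique(sets_a); sets_b <- unique(sets_b)
  summarize <- function(a, b) {
    shared <- intersect(a, b)
    un <- union(a, b)
    list(shared = length(shared), only_a = length(setdiff(a, b)),
         only_b = length(setdiff(b, a)), union = length(un),
         pct_shared = if (length(un) == 0) 0 else
           round_half_up(100 * length(shared) / length(un), 1))
  }
  out <- list(sets = summarize(sets_a, sets_b),
              genes = summarize(genes_a, genes_b),
              shared_genes = intersect(genes_a, genes_b),
              only_a_genes = setdiff(genes_a, genes_b),
              only_b_genes = setdiff(genes_b, genes_a))
  if (!is.null(gene_sets) && !is.null(universe)) {
    out$ora <- list(
      shared = ora(out$shared_genes, gene_sets, universe),
      only_a = ora(out$only_a_genes, gene_sets, universe),
      only_b = ora(out$only_b_genes, gene_sets, universe)
    )
  }
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between the gene list and each set, with Benjamini-Hochberg adjustment
#' across all tested sets.
#'
#' @param gene_list character vector (subset of `universe`).
#' @param gene_sets named list of member gene-id vectors.
#' @param universe character vector of all candidate genes.
#' @param fdr significance threshold on the adjusted q.
#' @return data frame `set_id`, `set_size`, `overlap`, `p`, `q`,
#'   `significant`.
#' @export
ora <- function(gene_list, gene_sets, universe, fdr = 0.05) {
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) stop("gene_list must be a subset of universe")
  M <- length(universe)
  nL <- length(gene_list)
  rows <- lapply(names(gene_sets), function(s) {
    members <- intersect(unique(gene_sets[[s]]), universe)
    K <- length(members)
    ov <- length(intersect(members, gene_list))
    p <- if (nL == 0L || ov == 0L) 1 else
      stats::phyper(ov - 1, K, M - K, nL, lower.tail = FALSE)
    data.frame(set_id = s, set_size = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out
}

#' Gene-set similarity network table
#'
#' Plain node/edge tables for generic network viewers: significant sets as
#' nodes, Jaccard similarity of member genes as edges above a threshold.
#'
#' @param results an `enrichment_result` data frame.
#' @param gene_sets named list of member gene-id vectors.
#' @param fdr significance threshold.
#' @param jaccard_min minimum Jaccard similarity for an edge.
#' @return list with data frames `nodes` (`set_id`, `nes`, `fdr_q`,
#'   `sign`, `size`) and `edges` (`from`, `to`, `jaccard`).
#' @export
enrichment_network <- function(results, gene_sets, fdr = 0.05, jaccard_min = 0.25) {
  sig <- results[!is.na(results$fdr_q) & results$fdr_q < fdr, , drop = FALSE]
  nodes <- sig[, c("set_id", "nes", "fdr_q", "sign", "size")]
  rownames(nodes) <- NULL
  edges <- data.frame(from = character(0), to = character(0),
                      jaccard = numeric(0), stringsAsFactors = FALSE)
  ids <- nodes$set_id
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        a <- unique(gene_sets[[ids[i]]])
        b <- unique(gene_sets[[ids[j]]])
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac >= jaccard_min)
          edges <- rbind(edges, data.frame(from = ids[i], to = ids[j],
                                           jaccard = jac))
      }
    }
  }
  list(nodes = nodes, edges = edges)
}
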