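# Validation statistics: sampling-without-replacement chance probability,
# evidence-weighted precision scores, signed correlation differences, and
# the bootstrap test on their mean.

#' Chance probability of drawing all candidates from a known pool
#'
#' Probability that `N` draws without replacement from a universe of `M`
#' genes all land inside a known pool of `K` genes:
#' `prod_{i=0..N-1} (K - i) / (M - i)`, which equals
#' `choose(K, N) / choose(M, N)`. Returns 0 when `N > K`; monotone
#' decreasing in `N` and increasing in `K`.
#'
#' @param N number of candidate genes found in the pool.
#' @param K pool size.
#' @param M universe size (>= K).
#' @return probability in `[0, 1]`.
#' @export
chance_probability <- function(N, K, M) {
  if (N < 0 || K < 0 || M < 1) stop("N, K must be >= 0 and M >= 1")
  if (K > M) stop("pool cannot exceed the universe")
  if (N > M) stop("cannot draw more genes than the universe holds")
  if (N == 0) return(1)
  if (N > K) return(0)
  i <- 0:(N - 1)
  prod((K - i) / (M - i))
}

#' Evidence-weighted precision scores for a candidate list
#'
#' Counts strong and weak evidence flags over the candidate genes, with
#' strong evidence worth a full point and weak evidence half a point:
#'
#'   memory_score = (0.5 Mem_w + Mem_s) /
#'                  ((0.5 Mem_w + Mem_s) + (0.5 Mot_w + Mot_s))
#'
#' and symmetrically for the motor score, so the two scores sum to 1
#' whenever any evidence exists. Candidate genes missing from the evidence
#' table contribute all-zero flags.
#'
#' @param cl character vector of candidate gene ids (or a candidate-list
#'   data frame with a `gene_id` column).
#' @param evidence data frame with `gene_id`, `mem_s`, `mem_w`, `mot_s`,
#'   `mot_w`.
#' @return list with `memory_score`, `motor_score`, `difference`
#'   (memory - motor), `counts`, and `defined` (`FALSE` with `NA` scores
#'   when there is no evidence at all).
#' @export
precision_scores <- function(cl, evidence) {
  genes <- if (is.data.frame(cl)) cl$gene_id else cl
  if (length(genes) == 0L) stop("candidate list is empty")
  i <- match(genes, evidence$gene_id)
  get <- function(col) {
    v <- evidence[[col]][i]
    v[is.na(v)] <- 0
    sum(v)
  }
  counts <- c(mem_s = get("mem_s"), mem_w = get("mem_w"),
              mot_s = get("mot_s"), mot_w = get("mot_w"))
  mem <- 0.5 * counts[["mem_w"]] + counts[["mem_s"]]
  mot <- 0.5 * counts[["mot_w"]] + counts[["mot_s"]]
  den <- mem + mot
  if (den == 0)
    return(list(memory_score = NA_real_, motor_score = NA_real_,
                difference = NA_real_, counts = counts, defined = FALSE))
  list(memory_score = mem / den, motor_score = mot / den,
       difference = (mem - mot) / den, counts = counts, defined = TRUE)
}

#' Signed correlation differences between two analyses
#'
#' For each gene, the difference between its correlation in the target
#' analysis and in the control analysis (`r_target - r_control`); for genes
#' coming from a negatively correlated list the difference is multiplied by
#' -1 so that a positive value always counts toward the method, consistent
#' with the positive lists. Genes missing from either ranked list are
#' excluded and recorded in attribute `excluded`.
#'
#' @param target_list,control_list ranked list data frames sharing a gene
#'   universe (e.g. memory as target and motor as control, or vice versa).
#' @param genes character vector of member genes of the significant sets
#'   under study.
#' @param sign +1 for a positively enriched list, -1 for a negatively
#'   enriched list.
#' @return named numeric vector of differences.
#' @export
correlation_differences <- function(target_list, control_list, genes, sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  genes <- unique(genes)
  rt <- target_list$mean_r[match(genes, target_list$gene_id)]
  rc <- control_list$mean_r[match(genes, control_list$gene_id)]
  ok <- !is.na(rt) & !is.na(rc)
  d <- sign * (rt[ok] - rc[ok])
  names(d) <- genes[ok]
  attr(d, "excluded") <- genes[!ok]
  d
}

#' Bootstrap test on the mean correlation difference
#'
#' Repeatedly subsamples the differences (without replacement by default)
#' to `n_sub` values, records each subsample's mean, and summarizes the
#' distribution by its mean and central 95% interval (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics). The mean
#' difference is deemed significantly different from the zero baseline when
#' the interval strictly excludes 0.
#'
#' @param differences numeric vector from [correlation_differences()].
#' @param n_sub subsample size (<= `length(differences)`).
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @param replace sample with replacement within an iteration.
#' @return list with `boot_mean`, `pct_2_5`, `pct_97_5`, `significant`,
#'   `n_sub`, `n_iter`.
#' @export
bootstrap_difference <- function(differences, n_sub, n_iter = 10000, seed = 1,
                                 replace = FALSE) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (!replace && n_sub > length(differences))
    stop("n_sub exceeds the number of differences")
  set.seed(seed)
  means <- vapply(seq_len(n_iter),
                  function(i) mean(sample(differences, n_sub, replace = replace)),
                  numeric(1))
  qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  list(boot_mean = mean(means), pct_2_5 = qs[1], pct_97_5 = qs[2],
       significant = qs[1] > 0 || qs[2] < 0,
       n_sub = n_sub, n_iter = n_iter)
}

#' Validation report for a set of candidate lists
#'
#' Bundles, per candidate list, the precision scores against an evidence
#' table and the chance probability of its pool hits, ready to serialize as
#' JSON.
#'
#' @param candidate_lists named list of candidate-list data frames (or
#'   gene-id vectors).
#' @param evidence evidence data frame (see [precision_scores()]).
#' @param pool character vector of known function-related genes.
#' @param universe_size number of genes analyzed.
#' @return list of per-list summaries.
#' @export
validation_report <- function(candidate_lists, evidence, pool, universe_size) {
  lapply(candidate_lists, function(cl) {
    genes <- if (is.data.frame(cl)) cl$gene_id else cl
    hits <- sum(genes %in% pool)
    ps <- precision_scores(genes, evidence)
    list(n_candidates = length(genes),
         n_pool_hits = hits,
         chance_probability = chance_probability(hits, length(pool), universe_size),
         memory_score = ps$memory_score,
         motor_score = ps$motor_score,
         difference = ps$difference)
  })
}
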