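# Per-gene spatial similarity between smoothed expression and map z across
# retained samples, fit per donor and combined across donors by an
# approximate random-effects mean into a ranked gene list.

#' Ordinary least-squares fit of expression on map z for one donor
#'
#' Each data point is a point in space with a normalized expression value
#' and a map z score; the fit captures one donor's spatial relationship for
#' one gene. Slope and intercept are modeled per donor; the Pearson
#' correlation is the statistic carried forward.
#'
#' @param expr numeric vector of expression values.
#' @param z numeric vector of map z scores, same length (n >= 3).
#' @return list with `slope`, `intercept`, `r`, `n_points`; `r` is `NA`
#'   when either vector has zero variance.
#' @export
donor_fit <- function(expr, z) {
  stopifnot(length(expr) == length(z))
  n <- length(expr)
  if (n < 3L) stop("donor fit needs at least 3 points")
  sz <- stats::sd(z)
  se <- stats::sd(expr)
  if (is.na(sz) || sz == 0 || is.na(se) || se == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n_points = n))
  cv <- stats::cov(expr, z)
  slope <- cv / sz^2
  list(slope = slope,
       intercept = mean(expr) - slope * mean(z),
       r = cv / (se * sz),
       n_points = n)
}

# Pearson r of every gene row against z, NA for zero-variance rows.
gene_cor <- function(expr, z) {
  n <- length(z)
  ce <- expr - rowMeans(expr)
  cz <- z - mean(z)
  den <- sqrt(rowSums(ce^2) * sum(cz^2))
  r <- as.numeric(ce %*% cz) / den
  r[den == 0 | !is.finite(den)] <- NA_real_
  names(r) <- rownames(expr)
  r
}

#' Combine per-donor correlations into a random-effects mean
#'
#' The approximate random-effects combination is the unweighted arithmetic
#' mean of the valid per-donor Pearson correlations (each donor's slope and
#' intercept having been fit individually). Genes with fewer than two valid
#' donors are excluded: a single-donor mean is not a random-effects
#' statistic. Optionally averages on the Fisher z scale.
#'
#' @param r_by_donor numeric matrix, genes x donors, of per-donor
#'   correlations (`NA` where a donor's fit was invalid).
#' @param fisher if `TRUE`, average `atanh(r)` and back-transform.
#' @return data frame with `gene_id`, `mean_r`, `n_donors_used`; excluded
#'   genes are listed in attribute `excluded_genes`.
#' @export
random_effects_mean <- function(r_by_donor, fisher = FALSE) {
  valid <- !is.na(r_by_donor)
  n_used <- rowSums(valid)
  if (fisher) {
    zmat <- atanh(pmin(pmax(r_by_donor, -1 + 1e-12), 1 - 1e-12))
    mean_r <- tanh(rowMeans(zmat, na.rm = TRUE))
  } else {
    mean_r <- rowMeans(r_by_donor, na.rm = TRUE)
  }
  keep <- n_used >= 2L
  out <- data.frame(gene_id = rownames(r_by_donor)[keep],
                    mean_r = mean_r[keep],
                    n_donors_used = n_used[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- rownames(r_by_donor)[!keep]
  out
}

#' Rank genes by random-effects mean correlation
#'
#' Orders genes descending by `mean_r`, breaking ties by gene id, and
#' reports the counts of positive and negative mean correlations.
#'
#' @param correlations data frame from [random_effects_mean()].
#' @return data frame (`rank`, `gene_id`, `mean_r`, `n_donors_used`)
#'   with attributes `n_positive` and `n_negative`.
#' @export
rank_list <- function(correlations) {
  ord <- order(-correlations$mean_r, correlations$gene_id)
  out <- correlations[ord, , drop = FALSE]
  out <- cbind(data.frame(rank = seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$mean_r > 0)
  attr(out, "n_negative") <- sum(out$mean_r < 0)
  out
}

#' Spatial correlation analysis for one compartment
#'
#' Computes per-donor, per-gene Pearson correlations between smoothed
#' expression and map z, combines donors with [random_effects_mean()], and
#' ranks the genes. Donor-compartments with fewer than 3 retained samples
#' are skipped (r is degenerate below that).
#'
#' @param paired output of [pair_samples()].
#' @param compartment `"cortical"` or `"subcortical"`.
#' @param fisher passed to [random_effects_mean()].
#' @return ranked list data frame (see [rank_list()]).
#' @export
spatial_correlation <- function(paired, compartment, fisher = FALSE) {
  donors <- names(paired)
  cols <- list()
  for (d in donors) {
    pc <- paired[[d]][[compartment]]
    if (is.null(pc) || length(pc$z) < 3L) next
    cols[[d]] <- gene_cor(pc$expr, pc$z)
  }
  if (length(cols) < 2L) stop("need >= 2 donors with usable samples")
  r_by_donor <- do.call(cbind, cols)
  rank_list(random_effects_mean(r_by_donor, fisher = fisher))
}

#' Write / read a ranked gene list
#'
#' Tab-separated with columns `rank`, `gene_id`, `mean_r`,
#' `n_donors_used`.
#'
#' @param ranked ranked list data frame.
#' @param path file path.
#' @return `path` (write) or the ranked list (read).
#' @export
write_ranked_list <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(out, "n_positive") <- sum(out$mean_r > 0)
  attr(out, "n_negative") <- sum(out$mean_r < 0)
  out
}
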