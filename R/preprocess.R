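# Probe-level donor matrices -> one gene-level, per-donor z-scored matrix
# per compartment: background filtering, differential-stability probe
# selection, and donor- and compartment-wise normalization.

#' Construct a probe-level expression matrix for one donor
#'
#' @param probe_id character vector of probe identifiers (one per row).
#' @param gene_id character vector mapping each probe to exactly one gene.
#' @param donor_id donor identifier.
#' @param values numeric matrix, probes x samples.
#' @param above_background logical matrix of the same shape flagging
#'   samples in which the probe exceeded background expression.
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(probe_id, gene_id, donor_id, values, above_background) {
  values <- as.matrix(values)
  above_background <- as.matrix(above_background)
  stopifnot(length(probe_id) == nrow(values),
            length(gene_id) == length(probe_id),
            all(dim(values) == dim(above_background)))
  rownames(values) <- probe_id
  rownames(above_background) <- probe_id
  structure(list(probe_id = probe_id, gene_id = gene_id, donor_id = donor_id,
                 values = values, above_background = above_background),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: donor %s, %d probes (%d genes) x %d samples\n",
              x$donor_id, nrow(x$values), length(unique(x$gene_id)),
              ncol(x$values)))
  invisible(x)
}

#' Filter probes by above-background fraction
#'
#' Retains exactly the probes whose fraction of above-background samples is
#' at least 0.5, computed over all of the donor's samples. Probes below
#' background in half or more of the samples are excluded.
#'
#' @param pm a [probe_matrix()].
#' @return the filtered `probe_matrix`, with attribute `dropped` listing
#'   removed probe ids.
#' @export
filter_probes <- function(pm) {
  if (nrow(pm$values) == 0L) stop("no probes")
  frac <- rowMeans(pm$above_background)
  keep <- frac >= 0.5
  out <- probe_matrix(pm$probe_id[keep], pm$gene_id[keep], pm$donor_id,
                      pm$values[keep, , drop = FALSE],
                      pm$above_background[keep, , drop = FALSE])
  attr(out, "dropped") <- pm$probe_id[!keep]
  out
}

# probes kept only if they pass the background filter in every donor
filter_probes_all <- function(pms) {
  filtered <- lapply(pms, filter_probes)
  keep <- Reduce(intersect, lapply(filtered, function(x) x$probe_id))
  lapply(filtered, function(x) {
    i <- match(keep, x$probe_id)
    probe_matrix(x$probe_id[i], x$gene_id[i], x$donor_id,
                 x$values[i, , drop = FALSE],
                 x$above_background[i, , drop = FALSE])
  })
}

#' Differential stability of each probe
#'
#' Expression is averaged within shared region labels per donor; the
#' differential stability (DS) of a probe is the mean over all donor pairs
#' of the Pearson correlation between the two donors' region-mean vectors,
#' restricted to regions sampled in both. Higher DS means a more
#' reproducible spatial expression pattern across donors. Donor pairs
#' sharing fewer than two regions are excluded; a probe with no valid pair
#' (or zero variance in every pair) gets `NA`.
#'
#' @param pms list of [probe_matrix()] objects, one per donor, sharing a
#'   probe universe.
#' @param samples sample table with `sample_id`, `donor_id`,
#'   `region_label`.
#' @return named numeric vector of DS scores, one per probe.
#' @export
differential_stability <- function(pms, samples) {
  if (length(pms) < 2L) stop("differential stability needs >= 2 donors")
  region_means <- lapply(pms, function(pm) {
    smp <- samples[match(colnames(pm$values), samples$sample_id), ]
    reg <- smp$region_label
    regs <- sort(unique(reg))
    out <- sapply(regs, function(r) rowMeans(pm$values[, reg == r, drop = FALSE]))
    if (is.null(dim(out))) out <- matrix(out, nrow = nrow(pm$values),
                                         dimnames = list(pm$probe_id, regs))
    out
  })
  probes <- pms[[1]]$probe_id
  pairs <- utils::combn(length(pms), 2, simplify = FALSE)
  acc <- matrix(0, nrow = length(probes), ncol = 0)
  for (pr in pairs) {
    a <- region_means[[pr[1]]]
    b <- region_means[[pr[2]]]
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) < 2L) next
    acc <- cbind(acc, row_cor(a[, shared, drop = FALSE], b[, shared, drop = FALSE]))
  }
  if (ncol(acc) == 0L) {
    ds <- rep(NA_real_, length(probes))
  } else {
    ds <- rowMeans(acc, na.rm = TRUE)
    ds[!is.finite(ds)] <- NA_real_
  }
  names(ds) <- probes
  ds
}

# row-wise Pearson correlation between two matrices of identical shape
row_cor <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  num <- rowSums(ca * cb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Select one probe per gene by differential stability
#'
#' For each gene, picks the surviving probe with the highest DS score; ties
#' are broken by the lexicographically smallest probe id. Genes whose DS
#' scores are all missing are dropped (recorded in attribute
#' `dropped_genes`).
#'
#' @param gene_id character vector mapping probes to genes, parallel to
#'   `ds`.
#' @param ds named numeric vector of DS scores from
#'   [differential_stability()].
#' @return data frame with columns `gene_id`, `probe_id`, `ds`.
#' @export
select_probes <- function(gene_id, ds) {
  stopifnot(length(gene_id) == length(ds))
  probe_id <- names(ds)
  ord <- order(gene_id, -ifelse(is.na(ds), -Inf, ds), probe_id)
  g <- gene_id[ord]
  first <- !duplicated(g)
  sel <- data.frame(gene_id = g[first], probe_id = probe_id[ord][first],
                    ds = ds[ord][first], stringsAsFactors = FALSE)
  bad <- is.na(sel$ds)
  out <- sel[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- sel$gene_id[bad]
  out
}

#' Z-score a gene-level matrix within donor and compartment
#'
#' For each gene row, subtracts the mean and divides by the sample standard
#' deviation (n - 1 denominator) across the samples of one donor and one
#' compartment. Zero-variance rows are set to all-zero and flagged. A
#' donor-compartment with a single sample cannot be normalized.
#'
#' @param values numeric matrix, genes x samples (one donor, one
#'   compartment).
#' @return matrix of z scores with attribute `zero_variance` (logical per
#'   gene).
#' @export
zscore_genes <- function(values) {
  if (ncol(values) < 2L) stop("cannot normalize")
  mu <- rowMeans(values)
  sdv <- apply(values, 1, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  z <- (values - mu) / ifelse(flat, 1, sdv)
  z[flat, ] <- 0
  attr(z, "zero_variance") <- flat
  z
}

#' Full preprocessing of a probe-level study
#'
#' Applies the background filter in every donor, computes differential
#' stability on the shared surviving probes, selects one probe per gene,
#' collapses to gene level, and z-scores each donor's cortical and
#' subcortical samples separately. Genes must survive in all donors so that
#' every donor shares one gene universe.
#'
#' @param pms list of [probe_matrix()] objects, one per donor.
#' @param samples sample table (see [generate_donor_samples()]).
#' @return list with `matrices[[donor]][[compartment]]` (gene x sample
#'   z-score matrices), `selection` (probe-per-gene data frame), and `qc`
#'   (dropped probes/genes and zero-variance flags).
#' @export
preprocess_study <- function(pms, samples) {
  filtered <- filter_probes_all(pms)
  if (nrow(filtered[[1]]$values) == 0L) stop("no probes survive the background filter")
  ds <- differential_stability(filtered, samples)
  sel <- select_probes(filtered[[1]]$gene_id, ds)
  qc <- list(
    dropped_probes = lapply(pms, function(pm) setdiff(pm$probe_id, filtered[[1]]$probe_id)),
    dropped_genes = attr(sel, "dropped_genes"),
    zero_variance = list()
  )
  matrices <- list()
  for (d in names(filtered)) {
    pm <- filtered[[d]]
    i <- match(sel$probe_id, pm$probe_id)
    gene_vals <- pm$values[i, , drop = FALSE]
    rownames(gene_vals) <- sel$gene_id
    smp <- samples[match(colnames(gene_vals), samples$sample_id), ]
    matrices[[d]] <- list()
    for (cm in unique(smp$compartment)) {
      sub <- gene_vals[, smp$compartment == cm, drop = FALSE]
      z <- zscore_genes(sub)
      qc$zero_variance[[paste(d, cm, sep = "_")]] <-
        sel$gene_id[attr(z, "zero_variance")]
      matrices[[d]][[cm]] <- z
    }
  }
  list(matrices = matrices, selection = sel, qc = qc)
}
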