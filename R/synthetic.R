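# Synthetic study generator: a term map with positive-z foci, donor sample
# points in a shared 3D space, probe-level expression with genes planted to
# correlate spatially with the map, a gene-set library enriched in the
# planted genes, and known-gene pools with literature-style evidence flags.
# Everything is driven by a single master seed so downstream stages can be
# scored against the planted ground truth.

#' Configuration for the synthetic study generator
#'
#' Captures the data regime the pipeline expects: several donors each
#' contributing sparse expression samples in a common space, a z-score term
#' map with positive foci, gene expression planted to track the map at a
#' chosen correlation, probe multiplicity per gene with one low-noise probe
#' (the intended differential-stability winner), cortical and subcortical
#' compartments with distinct baselines, and gene sets enriched in the
#' planted genes.
#'
#' @param n_donors number of donors (>= 2).
#' @param n_genes number of genes in the universe.
#' @param probes_per_gene probes measured per gene (>= 1); probe 1 of each
#'   gene carries low measurement noise and is the intended winner of
#'   differential-stability probe selection.
#' @param n_samples_per_donor_per_compartment sample points per donor in
#'   each of the cortical and subcortical compartments.
#' @param volume_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param n_foci number of spherical positive-z foci (>= 0; 0 gives an
#'   all-zero map).
#' @param focus_radius_mm radius of each focus in mm.
#' @param n_planted_per_sign number of positively and of negatively planted
#'   genes when explicit lists are not supplied.
#' @param planted_positive_genes,planted_negative_genes optional explicit
#'   gene-id character vectors; must be disjoint.
#' @param effect_rho target spatial correlation of planted genes with the
#'   standardized map value, in `[-1, 1]`.
#' @param noise_sd standard deviation of expression noise.
#' @param n_gene_sets total gene sets in the library.
#' @param n_planted_sets how many sets are planted as enriched (alternating
#'   positive/negative sign).
#' @param planted_set_fraction fraction of a planted set's members drawn
#'   from the planted-gene pool of its sign.
#' @param set_size_range size range for null sets.
#' @param planted_set_size_range size range for planted sets.
#' @param probe_good_sd measurement noise sd of each gene's first probe.
#' @param probe_decoy_sd measurement noise sd of the remaining probes.
#' @param bg_fail_fraction fraction of decoy probes flagged below
#'   background in more than half of the samples of every donor.
#' @param neg_voxel_fraction fraction of off-focus voxels given scattered
#'   negative z scores.
#' @param region_grid the volume is cut into `region_grid^3` blocks used as
#'   shared anatomical region labels.
#' @param pool_extra_fraction fraction of non-planted genes added to the
#'   known-memory pool (the motor pool is a disjoint draw of the same size).
#' @param seed master seed; fixed per-stage offsets derive stage seeds.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_donors = 4,
                             n_genes = 2000,
                             probes_per_gene = 3,
                             n_samples_per_donor_per_compartment = 100,
                             volume_shape = c(40L, 40L, 40L),
                             voxel_size_mm = 2,
                             n_foci = 4,
                             focus_radius_mm = 10,
                             n_planted_per_sign = 60,
                             planted_positive_genes = NULL,
                             planted_negative_genes = NULL,
                             effect_rho = 0.8,
                             noise_sd = 1,
                             n_gene_sets = 50,
                             n_planted_sets = 5,
                             planted_set_fraction = 0.9,
                             set_size_range = c(15, 100),
                             planted_set_size_range = c(40, 60),
                             probe_good_sd = 0.1,
                             probe_decoy_sd = 2,
                             bg_fail_fraction = 0.3,
                             neg_voxel_fraction = 0.02,
                             region_grid = 4,
                             pool_extra_fraction = 0.05,
                             seed = 1) {
  cfg <- list(
    n_donors = as.integer(n_donors), n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_samples_per_donor_per_compartment = as.integer(n_samples_per_donor_per_compartment),
    volume_shape = as.integer(volume_shape), voxel_size_mm = voxel_size_mm,
    n_foci = as.integer(n_foci), focus_radius_mm = focus_radius_mm,
    n_planted_per_sign = as.integer(n_planted_per_sign),
    planted_positive_genes = planted_positive_genes,
    planted_negative_genes = planted_negative_genes,
    effect_rho = effect_rho, noise_sd = noise_sd,
    n_gene_sets = as.integer(n_gene_sets),
    n_planted_sets = as.integer(n_planted_sets),
    planted_set_fraction = planted_set_fraction,
    set_size_range = as.integer(set_size_range),
    planted_set_size_range = as.integer(planted_set_size_range),
    probe_good_sd = probe_good_sd, probe_decoy_sd = probe_decoy_sd,
    bg_fail_fraction = bg_fail_fraction,
    neg_voxel_fraction = neg_voxel_fraction,
    region_grid = as.integer(region_grid),
    pool_extra_fraction = pool_extra_fraction,
    seed = as.integer(seed)
  )
  if (cfg$n_donors < 2L) stop("n_donors must be >= 2")
  if (cfg$probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 1L))
    stop("volume_shape must be 3 positive voxel counts")
  if (cfg$n_foci < 0L) stop("n_foci must be >= 0")
  if (abs(cfg$effect_rho) > 1) stop("effect_rho must lie in [-1, 1]")
  if (cfg$planted_set_fraction < 0 || cfg$planted_set_fraction > 1)
    stop("planted_set_fraction must lie in [0, 1]")
  if (!is.null(planted_positive_genes) && !is.null(planted_negative_genes) &&
      length(intersect(planted_positive_genes, planted_negative_genes)) > 0)
    stop("planted gene lists must be disjoint")
  class(cfg) <- "synthetic_config"
  cfg
}

gene_ids <- function(cfg) {
  sprintf("G%0*d", max(4L, nchar(cfg$n_genes)), seq_len(cfg$n_genes))
}

donor_ids <- function(cfg) sprintf("D%02d", seq_len(cfg$n_donors))

#' Planted ground truth for a synthetic study
#'
#' Decides which genes carry planted spatial signal (and with which sign),
#' which gene sets will be planted as enriched, and the known-gene pools
#' used by the validation stage. The planted gene identities are drawn at
#' random from the universe so they are not recoverable from file ordering.
#'
#' @param cfg a [synthetic_config()].
#' @return list with elements `genes` (data frame: `gene_id`,
#'   `planted_sign` in -1/0/+1, `target_rho`), `pools` (character vectors
#'   `memory`, `motor`) and `set_info` placeholder filled by
#'   [generate_gene_sets()].
#' @export
planted_truth <- function(cfg) {
  set.seed(child_seed(cfg$seed, 11))
  ids <- gene_ids(cfg)
  pos <- cfg$planted_positive_genes
  neg <- cfg$planted_negative_genes
  if (is.null(pos) || is.null(neg)) {
    picked <- sample(ids, 2L * cfg$n_planted_per_sign)
    if (is.null(pos)) pos <- picked[seq_len(cfg$n_planted_per_sign)]
    if (is.null(neg)) neg <- setdiff(picked, pos)[seq_len(cfg$n_planted_per_sign)]
  }
  stopifnot(all(c(pos, neg) %in% ids), length(intersect(pos, neg)) == 0)
  sign <- integer(length(ids))
  sign[match(pos, ids)] <- 1L
  sign[match(neg, ids)] <- -1L
  genes <- data.frame(
    gene_id = ids,
    planted_sign = sign,
    target_rho = ifelse(sign == 0L, 0, cfg$effect_rho),
    stringsAsFactors = FALSE
  )
  planted <- c(pos, neg)
  nonplanted <- setdiff(ids, planted)
  n_extra <- round(cfg$pool_extra_fraction * length(nonplanted))
  memory_pool <- c(planted, sample(nonplanted, n_extra))
  motor_pool <- sample(setdiff(ids, memory_pool),
                       min(length(memory_pool), cfg$n_genes - length(memory_pool)))
  list(genes = genes, pools = list(memory = memory_pool, motor = motor_pool))
}

# compartment of each voxel: upper half of the third axis is "cortical"
voxel_compartments <- function(shape) {
  k <- rep(seq_len(shape[3]), each = shape[1] * shape[2])
  ifelse(k > shape[3] / 2, "cortical", "subcortical")
}

#' Generate a synthetic functional-association term map
#'
#' Builds a volume of zeros, adds `n_foci` spherical positive-z foci whose
#' peak z is drawn uniformly in `[2, 8]` and decays linearly to a strictly
#' positive floor at the sphere boundary, and scatters a small fraction of
#' negative-z voxels outside the foci. Focus centers alternate between the
#' cortical and subcortical halves of the volume so both compartments
#' contain positive voxels. The affine is diagonal with the volume centered
#' on the origin.
#'
#' @param cfg a [synthetic_config()].
#' @return a [term_map()] with attribute `foci` (data frame of centers,
#'   peak z and radius).
#' @export
generate_term_map <- function(cfg) {
  shape <- cfg$volume_shape
  vs <- cfg$voxel_size_mm
  extent <- shape * vs
  if (cfg$n_foci > 0 && cfg$focus_radius_mm > min(extent) / 2)
    stop("focus does not fit")
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -(shape - 1) * vs / 2
  values <- array(0, dim = shape)
  map <- term_map(values, affine)
  if (cfg$n_foci == 0L) return(map)

  set.seed(child_seed(cfg$seed, 23))
  centers <- voxel_centers(map)
  comp <- voxel_compartments(shape)
  r <- cfg$focus_radius_mm
  lo <- apply(centers, 2, min) + r
  hi <- apply(centers, 2, max) - r
  interior <- centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
    centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
    centers[, 3] >= lo[3] & centers[, 3] <= hi[3]
  foci <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0), peak = numeric(0))
  vals <- as.numeric(values)
  for (f in seq_len(cfg$n_foci)) {
    half <- if (f %% 2L == 1L) "cortical" else "subcortical"
    pool <- which(interior & comp == half)
    if (length(pool) == 0L) pool <- which(interior)
    if (length(pool) == 0L) stop("focus does not fit")
    ctr <- centers[sample(pool, 1L), ]
    peak <- stats::runif(1, 2, 8)
    d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 +
                (centers[, 3] - ctr[3])^2)
    inside <- d <= r
    vals[inside] <- pmax(vals[inside], peak * (1 - 0.9 * d[inside] / r))
    foci <- rbind(foci, data.frame(x = ctr[1], y = ctr[2], z = ctr[3], peak = peak))
  }
  bg <- which(vals == 0)
  n_neg <- round(cfg$neg_voxel_fraction * length(vals))
  if (n_neg > 0 && length(bg) > 0) {
    pick <- sample(bg, min(n_neg, length(bg)))
    vals[pick] <- -abs(stats::rnorm(length(pick)))
  }
  map$values <- array(vals, dim = shape)
  attr(map, "foci") <- foci
  map
}

#' Generate donor sample points
#'
#' For every donor and compartment, draws sample points without replacement
#' from the voxel centers of that compartment, stratified so that at least
#' half land inside positive-z voxels. Each sample gets a shared region
#' label from a block partition of the volume, used later for
#' differential-stability probe selection.
#'
#' @param cfg a [synthetic_config()].
#' @param map the [term_map()] the samples are drawn against.
#' @return data frame with columns `sample_id`, `donor_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `compartment`, `region_label`.
#' @export
generate_donor_samples <- function(cfg, map) {
  set.seed(child_seed(cfg$seed, 37))
  shape <- dim(map$values)
  centers <- voxel_centers(map)
  comp <- voxel_compartments(shape)
  pos <- as.numeric(map$values) > 0
  g <- cfg$region_grid
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  block <- function(v, n) pmin(g, ceiling(v * g / n))
  region_block <- (block(idx[, 1], shape[1]) - 1L) * g * g +
    (block(idx[, 2], shape[2]) - 1L) * g + block(idx[, 3], shape[3])

  n <- cfg$n_samples_per_donor_per_compartment
  out <- list()
  for (d in donor_ids(cfg)) {
    for (cm in c("cortical", "subcortical")) {
      if (n == 0L) next
      pool <- which(comp == cm)
      pos_pool <- pool[pos[pool]]
      bg_pool <- pool[!pos[pool]]
      n_pos <- min(ceiling(n / 2), n)
      if (length(pos_pool) < n_pos || length(bg_pool) < n - n_pos)
        stop("requested samples exceed available voxels in compartment ", cm)
      pick <- c(sample(pos_pool, n_pos), sample(bg_pool, n - n_pos))
      out[[paste(d, cm)]] <- data.frame(
        sample_id = sprintf("%s_%s_S%03d", d, substr(cm, 1, 3), seq_along(pick)),
        donor_id = d,
        x_mm = centers[pick, 1], y_mm = centers[pick, 2], z_mm = centers[pick, 3],
        compartment = cm,
        region_label = sprintf("%s_R%02d", cm, region_block[pick]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(0), donor_id = character(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      compartment = character(0), region_label = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate probe-level expression with planted spatial signal
#'
#' For a planted gene with target correlation `rho` and sign `s`, the
#' gene-level signal at a sample is `s * rho * z~ + sqrt(1 - rho^2) * e`,
#' where `z~` is the map z score at the sample standardized within that
#' donor and compartment and `e ~ Normal(0, noise_sd)`; non-planted genes
#' are pure noise. A gene- and compartment-specific baseline (removed later
#' by z-scoring) gives the compartments distinct expression levels. Each
#' gene is expanded to `probes_per_gene` probes: probe 1 adds little
#' measurement noise (the intended differential-stability winner), the rest
#' add heavy noise, and a configured fraction of those decoys is flagged
#' below background in more than half of each donor's samples.
#'
#' @param cfg a [synthetic_config()].
#' @param samples data frame from [generate_donor_samples()].
#' @param map the [term_map()].
#' @param truth output of [planted_truth()].
#' @return list with `matrices` (one `probe_matrix` per donor) and
#'   `probe_info` (data frame: `probe_id`, `gene_id`, `intended_winner`,
#'   `bg_fail`).
#' @export
generate_expression <- function(cfg, samples, map, truth) {
  ids <- truth$genes$gene_id
  np <- cfg$probes_per_gene
  probe_id <- as.vector(t(outer(ids, seq_len(np), function(g, j) sprintf("%s_P%d", g, j))))
  probe_gene <- rep(ids, each = np)
  probe_j <- rep(seq_len(np), times = length(ids))

  set.seed(child_seed(cfg$seed, 49))
  base_cort <- stats::rnorm(length(ids), 6, 1)
  base_sub <- base_cort + stats::rnorm(length(ids), 1.5, 0.5)
  bg_fail <- rep(FALSE, length(probe_id))
  decoys <- which(probe_j > 1L)
  if (length(decoys) > 0 && cfg$bg_fail_fraction > 0)
    bg_fail[sample(decoys, round(cfg$bg_fail_fraction * length(decoys)))] <- TRUE

  probe_info <- data.frame(probe_id = probe_id, gene_id = probe_gene,
                           intended_winner = probe_j == 1L, bg_fail = bg_fail,
                           stringsAsFactors = FALSE)

  set.seed(child_seed(cfg$seed, 51))
  sgn <- truth$genes$planted_sign
  rho <- truth$genes$target_rho
  matrices <- list()
  for (d in donor_ids(cfg)) {
    sd_idx <- which(samples$donor_id == d)
    smp <- samples[sd_idx, , drop = FALSE]
    ns <- nrow(smp)
    vox <- sample_to_voxel(as.matrix(smp[, c("x_mm", "y_mm", "z_mm")]), map,
                           sample_id = smp$sample_id)
    zraw <- map$values[vox]
    ztil <- numeric(ns)
    for (cm in unique(smp$compartment)) {
      i <- smp$compartment == cm
      zc <- zraw[i]
      s <- stats::sd(zc)
      ztil[i] <- if (is.na(s) || s == 0) 0 else (zc - mean(zc)) / s
    }
    signal <- matrix(stats::rnorm(length(ids) * ns, 0, cfg$noise_sd),
                     nrow = length(ids))
    planted <- which(sgn != 0L)
    for (gi in planted) {
      signal[gi, ] <- sgn[gi] * rho[gi] * ztil +
        sqrt(1 - rho[gi]^2) * stats::rnorm(ns, 0, cfg$noise_sd)
    }
    basemat <- outer(base_cort, as.numeric(smp$compartment == "cortical")) +
      outer(base_sub, as.numeric(smp$compartment != "cortical"))
    values <- matrix(0, nrow = length(probe_id), ncol = ns,
                     dimnames = list(probe_id, smp$sample_id))
    flags <- matrix(FALSE, nrow = length(probe_id), ncol = ns,
                    dimnames = list(probe_id, smp$sample_id))
    for (j in seq_len(np)) {
      rows <- which(probe_j == j)
      psd <- if (j == 1L) cfg$probe_good_sd else cfg$probe_decoy_sd
      values[rows, ] <- signal + basemat +
        matrix(stats::rnorm(length(rows) * ns, 0, psd), nrow = length(rows))
      p_above <- if (j == 1L) 0.97 else 0.9
      flags[rows, ] <- matrix(stats::runif(length(rows) * ns) < p_above,
                              nrow = length(rows))
    }
    if (any(bg_fail)) {
      rows <- which(bg_fail)
      flags[rows, ] <- matrix(stats::runif(length(rows) * ns) < 0.3,
                              nrow = length(rows))
    }
    matrices[[d]] <- probe_matrix(probe_id = probe_id, gene_id = probe_gene,
                                  donor_id = d, values = values,
                                  above_background = flags)
  }
  list(matrices = matrices, probe_info = probe_info)
}

#' Generate a gene-set library with planted enriched sets
#'
#' Planted sets draw a configured fraction of their members from the
#' planted-gene pool of their sign (alternating positive/negative across
#' planted sets, covering every planted gene at least once); null sets are
#' uniform draws from the universe. Set order and member order are shuffled
#' so planted sets are not identifiable from position.
#'
#' @param cfg a [synthetic_config()].
#' @param truth output of [planted_truth()].
#' @return list with `sets` (named list of member gene-id vectors) and
#'   `info` (data frame: `set_id`, `size`, `planted`, `sign`).
#' @export
generate_gene_sets <- function(cfg, truth) {
  set.seed(child_seed(cfg$seed, 67))
  ids <- truth$genes$gene_id
  if (max(cfg$set_size_range, cfg$planted_set_size_range) > length(ids))
    stop("set size exceeds gene universe")
  n_pl <- min(cfg$n_planted_sets, cfg$n_gene_sets)
  signs <- rep_len(c(1L, -1L), n_pl)
  sizes_pl <- sample(seq(cfg$planted_set_size_range[1], cfg$planted_set_size_range[2]),
                     n_pl, replace = TRUE)
  sets <- list()
  info <- list()
  for (s in c(1L, -1L)) {
    which_pl <- which(signs == s)
    if (length(which_pl) == 0L) next
    pool <- truth$genes$gene_id[truth$genes$planted_sign == s]
    m <- pmax(1L, round(cfg$planted_set_fraction * sizes_pl[which_pl]))
    if (sum(m) < length(pool))
      stop("planted sets too small to cover the planted pool; increase ",
           "n_planted_sets or planted_set_size_range")
    seqpool <- rep(sample(pool), length.out = sum(m))
    offset <- 0L
    for (i in seq_along(which_pl)) {
      k <- sizes_pl[which_pl[i]]
      members <- unique(seqpool[offset + seq_len(m[i])])
      offset <- offset + m[i]
      short <- m[i] - length(members)
      avail <- setdiff(pool, members)
      if (short > 0 && length(avail) > 0)
        members <- c(members, sample(avail, min(short, length(avail))))
      fill <- k - length(members)
      nonpool <- setdiff(ids, pool)
      if (fill > 0) members <- c(members, sample(nonpool, fill))
      key <- sprintf("pl_%d_%d", s, i)
      sets[[key]] <- sample(members)
      info[[key]] <- data.frame(size = k, planted = TRUE, sign = s)
    }
  }
  n_null <- cfg$n_gene_sets - length(sets)
  sizes_null <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                       max(0L, n_null), replace = TRUE)
  for (i in seq_len(max(0L, n_null))) {
    key <- sprintf("null_%d", i)
    sets[[key]] <- sample(ids, sizes_null[i])
    info[[key]] <- data.frame(size = sizes_null[i], planted = FALSE, sign = 0L)
  }
  ord <- sample(seq_along(sets))
  sets <- sets[ord]
  info <- do.call(rbind, info)[ord, , drop = FALSE]
  set_id <- sprintf("GS%03d", seq_along(sets))
  names(sets) <- set_id
  info <- cbind(data.frame(set_id = set_id, stringsAsFactors = FALSE), info)
  rownames(info) <- NULL
  list(sets = sets, info = info)
}

#' Generate a literature-style evidence table
#'
#' Assigns per-gene binary evidence flags (memory strong/weak, motor
#' strong/weak) consistent with the known-gene pools: planted genes receive
#' memory evidence with high probability, other pool members with moderate
#' probability, and genes outside a pool receive no flags for that
#' function. Strong and weak evidence for the same function are mutually
#' exclusive by construction.
#'
#' @param cfg a [synthetic_config()].
#' @param truth output of [planted_truth()].
#' @return data frame with columns `gene_id`, `mem_s`, `mem_w`, `mot_s`,
#'   `mot_w` (0/1 integers).
#' @export
generate_evidence_table <- function(cfg, truth) {
  set.seed(child_seed(cfg$seed, 79))
  ids <- truth$genes$gene_id
  planted <- truth$genes$planted_sign != 0L
  in_mem <- ids %in% truth$pools$memory
  in_mot <- ids %in% truth$pools$motor
  p_mem <- ifelse(planted, 0.9, ifelse(in_mem, 0.6, 0))
  has_mem <- stats::runif(length(ids)) < p_mem
  mem_strong <- stats::runif(length(ids)) < 0.5
  p_mot <- ifelse(in_mot, 0.6, 0)
  has_mot <- stats::runif(length(ids)) < p_mot
  mot_strong <- stats::runif(length(ids)) < 0.5
  data.frame(
    gene_id = ids,
    mem_s = as.integer(has_mem & mem_strong),
    mem_w = as.integer(has_mem & !mem_strong),
    mot_s = as.integer(has_mot & mot_strong),
    mot_w = as.integer(has_mot & !mot_strong),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under the master seed and returns the whole
#' study in memory: planted truth, term map, donor samples, probe-level
#' expression, gene-set library and evidence table.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_study` with elements `config`, `truth`,
#'   `map`, `samples`, `expression`, `probe_info`, `gene_sets`, `set_info`,
#'   `evidence`.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  truth <- planted_truth(cfg)
  map <- generate_term_map(cfg)
  samples <- generate_donor_samples(cfg, map)
  expr <- generate_expression(cfg, samples, map, truth)
  gs <- generate_gene_sets(cfg, truth)
  truth$set_info <- gs$info
  evidence <- generate_evidence_table(cfg, truth)
  structure(list(config = cfg, truth = truth, map = map, samples = samples,
                 expression = expr$matrices, probe_info = expr$probe_info,
                 gene_sets = gs$sets, set_info = gs$info, evidence = evidence),
            class = "synthetic_study")
}
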