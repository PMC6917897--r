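# The synthetic study generator: determinism, geometry of the term map,
# sample stratification, the planted expression model, gene-set planting,
# and the evidence table.

test_that("identical configs give identical studies (full determinism)", {
  cfg <- small_config(seed = 13)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$map$values, b$map$values)
  expect_identical(a$samples, b$samples)
  expect_identical(a$expression[[1]]$values, b$expression[[1]]$values)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$evidence, b$evidence)
})

test_that("term map geometry: no foci, fit check, and sphere rasterization", {
  cfg0 <- small_config(n_foci = 0)
  m0 <- generate_term_map(cfg0)
  expect_true(all(m0$values == 0))
  expect_identical(sum(m0$values > 0), 0L)

  expect_error(generate_term_map(small_config(focus_radius_mm = 200)),
               "focus does not fit")

  cfg <- synthetic_config(n_foci = 3, focus_radius_mm = 10, voxel_size_mm = 2,
                          volume_shape = c(40L, 40L, 40L), seed = 3)
  map <- generate_term_map(cfg)
  foci <- attr(map, "foci")
  centers <- voxel_centers(map)
  inside_any <- rep(FALSE, nrow(centers))
  for (f in seq_len(nrow(foci))) {
    d2 <- (centers[, 1] - foci$x[f])^2 + (centers[, 2] - foci$y[f])^2 +
      (centers[, 3] - foci$z[f])^2
    inside_any <- inside_any | d2 <= 10^2
  }
  expect_identical(sum(map$values > 0), sum(inside_any))
})

test_that("donor samples respect stratification and the affine round-trip", {
  cfg <- small_config(seed = 21)
  map <- generate_term_map(cfg)

  empty <- generate_donor_samples(small_config(n_samples_per_donor_per_compartment = 0), map)
  expect_identical(nrow(empty), 0L)

  smp <- generate_donor_samples(cfg, map)
  vox <- sample_to_voxel(as.matrix(smp[, c("x_mm", "y_mm", "z_mm")]), map,
                         sample_id = smp$sample_id)
  d <- dim(map$values)
  expect_true(all(vox[, 1] >= 1 & vox[, 1] <= d[1]))
  expect_true(all(vox[, 3] >= 1 & vox[, 3] <= d[3]))

  z <- map$values[attr(vox, "linear")]
  for (dn in unique(smp$donor_id)) {
    for (cm in c("cortical", "subcortical")) {
      i <- smp$donor_id == dn & smp$compartment == cm
      expect_gte(sum(z[i] > 0), ceiling(sum(i) / 2))
    }
  }

  tiny <- synthetic_config(volume_shape = c(4L, 4L, 4L), voxel_size_mm = 2,
                           n_foci = 1, focus_radius_mm = 2,
                           n_samples_per_donor_per_compartment = 100, seed = 1)
  expect_error(generate_donor_samples(tiny, generate_term_map(tiny)),
               "exceed")
})

test_that("noiseless planted expression is an exact affine image of map z", {
  cfg <- small_config(noise_sd = 0, effect_rho = 1, probes_per_gene = 1,
                      probe_good_sd = 0, seed = 5)
  truth <- planted_truth(cfg)
  map <- generate_term_map(cfg)
  smp <- generate_donor_samples(cfg, map)
  ex <- generate_expression(cfg, smp, map, truth)
  planted <- truth$genes[truth$genes$planted_sign != 0, ]
  pm <- ex$matrices[[1]]
  s <- smp[match(colnames(pm$values), smp$sample_id), ]
  vox <- sample_to_voxel(as.matrix(s[, c("x_mm", "y_mm", "z_mm")]), map)
  z <- map$values[attr(vox, "linear")]
  for (gi in sample(seq_len(nrow(planted)), 5)) {
    probe <- paste0(planted$gene_id[gi], "_P1")
    for (cm in c("cortical", "subcortical")) {
      i <- s$compartment == cm
      r <- cor(pm$values[probe, i], z[i]) * planted$planted_sign[gi]
      expect_equal(r, 1, tolerance = 1e-12)
    }
  }
})

test_that("non-planted genes have mean spatial correlation near zero", {
  cfg <- synthetic_config(n_donors = 2, n_genes = 2000, probes_per_gene = 1,
                          n_samples_per_donor_per_compartment = 100,
                          n_planted_per_sign = 10, n_planted_sets = 2,
                          planted_set_size_range = c(15, 20), seed = 31)
  truth <- planted_truth(cfg)
  map <- generate_term_map(cfg)
  smp <- generate_donor_samples(cfg, map)
  ex <- generate_expression(cfg, smp, map, truth)
  nulls <- paste0(truth$genes$gene_id[truth$genes$planted_sign == 0], "_P1")
  pm <- ex$matrices[[1]]
  s <- smp[match(colnames(pm$values), smp$sample_id), ]
  vox <- sample_to_voxel(as.matrix(s[, c("x_mm", "y_mm", "z_mm")]), map)
  z <- map$values[attr(vox, "linear")]
  i <- s$compartment == "cortical"
  r <- as.numeric(cor(t(pm$values[nulls, i]), z[i]))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("planted rho = 0.6 yields per-donor r in the sampling band", {
  cfg <- synthetic_config(n_donors = 2, n_genes = 200, n_planted_per_sign = 100,
                          probes_per_gene = 1, probe_good_sd = 0,
                          effect_rho = 0.6, noise_sd = 1,
                          n_samples_per_donor_per_compartment = 100,
                          n_planted_sets = 4, planted_set_size_range = c(40, 60),
                          seed = 11)
  truth <- planted_truth(cfg)
  map <- generate_term_map(cfg)
  smp <- generate_donor_samples(cfg, map)
  ex <- generate_expression(cfg, smp, map, truth)
  planted <- truth$genes[truth$genes$planted_sign != 0, ]
  rs <- c()
  for (d in names(ex$matrices)) {
    pm <- ex$matrices[[d]]
    s <- smp[match(colnames(pm$values), smp$sample_id), ]
    vox <- sample_to_voxel(as.matrix(s[, c("x_mm", "y_mm", "z_mm")]), map)
    z <- map$values[attr(vox, "linear")]
    for (cm in c("cortical", "subcortical")) {
      i <- s$compartment == cm
      r <- as.numeric(cor(t(pm$values[paste0(planted$gene_id, "_P1"), i]), z[i]))
      rs <- c(rs, r * planted$planted_sign)
    }
  }
  expect_gte(length(rs), 200)
  expect_gte(mean(rs >= 0.45 & rs <= 0.72), 0.95)
})

test_that("gene sets cover planted genes and respect the planted fraction", {
  cfg <- small_config(seed = 17)
  truth <- planted_truth(cfg)
  gs <- generate_gene_sets(cfg, truth)
  planted_genes <- truth$genes$gene_id[truth$genes$planted_sign != 0]
  planted_sets <- gs$info$set_id[gs$info$planted]
  in_planted_sets <- unique(unlist(gs$sets[planted_sets]))
  expect_true(all(planted_genes %in% in_planted_sets))

  cfg1 <- small_config(planted_set_fraction = 1, n_planted_per_sign = 40,
                       n_planted_sets = 4, planted_set_size_range = c(20, 30))
  truth1 <- planted_truth(cfg1)
  gs1 <- generate_gene_sets(cfg1, truth1)
  for (sid in gs1$info$set_id[gs1$info$planted]) {
    s <- gs1$info$sign[gs1$info$set_id == sid]
    pool <- truth1$genes$gene_id[truth1$genes$planted_sign == s]
    expect_true(all(gs1$sets[[sid]] %in% pool))
  }

  expect_error(generate_gene_sets(small_config(set_size_range = c(500, 600)),
                                  truth),
               "exceeds")
})

test_that("null-set overlap with the planted pool matches the binomial expectation", {
  cfg <- synthetic_config(n_genes = 1000, n_planted_per_sign = 50,
                          n_gene_sets = 505, n_planted_sets = 5,
                          planted_set_size_range = c(40, 60),
                          set_size_range = c(15, 100), seed = 23)
  truth <- planted_truth(cfg)
  gs <- generate_gene_sets(cfg, truth)
  pool <- truth$genes$gene_id[truth$genes$planted_sign != 0]
  p <- length(pool) / cfg$n_genes
  null_ids <- gs$info$set_id[!gs$info$planted]
  expect_gte(length(null_ids), 500)
  k <- lengths(gs$sets[null_ids])
  observed <- sum(vapply(gs$sets[null_ids],
                         function(s) length(intersect(s, pool)), numeric(1)))
  expected <- sum(k) * p
  sd3 <- 3 * sqrt(sum(k) * p * (1 - p))
  expect_lt(abs(observed - expected), sd3)
})

test_that("evidence flags are pool-consistent, exclusive, and enriched in planted genes", {
  cfg <- small_config(seed = 29)
  truth <- planted_truth(cfg)
  ev <- generate_evidence_table(cfg, truth)
  outside <- !(ev$gene_id %in% truth$pools$memory) &
    !(ev$gene_id %in% truth$pools$motor)
  expect_true(all(rowSums(ev[outside, c("mem_s", "mem_w", "mot_s", "mot_w")]) == 0))
  expect_true(all(!(ev$mem_s == 1 & ev$mem_w == 1)))
  expect_true(all(!(ev$mot_s == 1 & ev$mot_w == 1)))
  planted <- truth$genes$planted_sign != 0
  prev_planted <- mean(ev$mem_s[planted] | ev$mem_w[planted])
  prev_null <- mean(ev$mem_s[!planted] | ev$mem_w[!planted])
  expect_gte(prev_planted, 5 * prev_null)
})

test_that("a written study round-trips and hides planted genes in file order", {
  cfg <- small_config(seed = 37)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)

  expect_false(identical(rownames(back$expression[[1]]$values),
                         rownames(st$expression[[1]]$values)))
  d1 <- names(st$expression)[1]
  reord <- back$expression[[d1]]$values[rownames(st$expression[[d1]]$values), ]
  expect_equal(reord, st$expression[[d1]]$values, tolerance = 1e-12)
  expect_identical(back$gene_sets[names(st$gene_sets)], st$gene_sets)
  expect_equal(back$map$values, st$map$values, tolerance = 1e-6)
  expect_identical(back$samples$sample_id, st$samples$sample_id)
})
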