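# Plain-text interchange: GMT gene-set libraries and the on-disk layout of
# a synthetic study (sample annotation TSV, per-donor probe CSVs, NIfTI
# term map, pools/evidence TSVs, truth JSON).

#' Write a gene-set library in GMT format
#'
#' One set per line: id, description, then tab-separated member gene ids.
#'
#' @param gene_sets named list of member gene-id vectors.
#' @param path output path.
#' @param descriptions optional character vector parallel to `gene_sets`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' @param path GMT file.
#' @return named list of member gene-id vectors, with attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write a synthetic study to a directory
#'
#' Produces the plain-text inputs the pipeline consumes: `samples.tsv`,
#' one `probes_<donor>.csv` and `background_<donor>.csv` per donor (rows
#' are probes, shuffled so planted genes are not identifiable from file
#' order), `probe_annotation.tsv`, `term_map.nii.gz`, `gene_sets.gmt`,
#' `pools.tsv`, `evidence.tsv` and `truth.json`.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_term_map(study$map, file.path(dir, "term_map.nii.gz"))
  set.seed(child_seed(study$config$seed, 91))
  ord <- sample(nrow(study$probe_info))
  utils::write.table(study$probe_info[ord, c("probe_id", "gene_id")],
                     file.path(dir, "probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(study$expression)) {
    pm <- study$expression[[d]]
    utils::write.csv(as.data.frame(pm$values[ord, , drop = FALSE]),
                     file.path(dir, sprintf("probes_%s.csv", d)))
    utils::write.csv(as.data.frame(pm$above_background[ord, , drop = FALSE] * 1L),
                     file.path(dir, sprintf("background_%s.csv", d)))
  }
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  pools <- data.frame(
    gene_id = study$truth$genes$gene_id,
    memory_pool = as.integer(study$truth$genes$gene_id %in% study$truth$pools$memory),
    motor_pool = as.integer(study$truth$genes$gene_id %in% study$truth$pools$motor)
  )
  utils::write.table(pools, file.path(dir, "pools.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(genes = study$truth$genes, set_info = study$set_info,
         pools = study$truth$pools),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a synthetic study back from a directory
#'
#' Inverse of [write_study()] up to row order; probe matrices are restored
#' against the shuffled annotation.
#'
#' @param dir directory written by [write_study()].
#' @return list with `samples`, `map`, `expression` (probe matrices),
#'   `probe_info`, `gene_sets`, `pools`, `evidence`, `truth`.
#' @export
read_study <- function(dir) {
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  map <- read_term_map(file.path(dir, "term_map.nii.gz"))
  anno <- utils::read.delim(file.path(dir, "probe_annotation.tsv"),
                            stringsAsFactors = FALSE)
  donor_files <- list.files(dir, pattern = "^probes_.*\\.csv$")
  donors <- sub("^probes_(.*)\\.csv$", "\\1", donor_files)
  expression <- list()
  for (d in donors) {
    vals <- as.matrix(utils::read.csv(file.path(dir, sprintf("probes_%s.csv", d)),
                                      row.names = 1, check.names = FALSE))
    flags <- as.matrix(utils::read.csv(file.path(dir, sprintf("background_%s.csv", d)),
                                       row.names = 1, check.names = FALSE)) > 0
    expression[[d]] <- probe_matrix(rownames(vals),
                                    anno$gene_id[match(rownames(vals), anno$probe_id)],
                                    d, vals, flags)
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(samples = samples, map = map, expression = expression,
       probe_info = anno, gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
       pools = utils::read.delim(file.path(dir, "pools.tsv"), stringsAsFactors = FALSE),
       evidence = utils::read.delim(file.path(dir, "evidence.tsv"), stringsAsFactors = FALSE),
       truth = truth)
}

#' Write enrichment results as TSV
#'
#' Leading-edge gene ids are semicolon-joined into a single column.
#'
#' @param results an `enrichment_result` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  flat <- results
  flat$leading_edge <- vapply(results$leading_edge, paste, character(1),
                              collapse = ";")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
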