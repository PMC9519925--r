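## Readers and writers for the plain-text interchange formats: AHBA-dialect
## CSV triplets, rsFC TSVs, GMT gene sets, genotype matrices, geometry and
## expression TSVs, and JSON truth records.

#' Write / read a parcel geometry as TSV
#' @param geometry a `parcel_geometry`.
#' @param path file path.
#' @return `read_geometry` returns a `parcel_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.table(geometry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(g) <- c("parcel_geometry", "data.frame")
  g
}

#' Write a donor sample set as an AHBA-dialect CSV triplet
#'
#' Produces `SampleAnnot.csv` (sample_id, mni_x/y/z, hemisphere),
#' `MicroarrayExpression.csv` (probe_id + one column per sample) and
#' `Probes.csv` (probe_id, gene_id) under `dir/<donor_id>/`.
#'
#' @param donor a donor sample set.
#' @param dir output directory.
#' @return the donor directory path, invisibly.
#' @export
write_donor_csv <- function(donor, dir) {
  d <- file.path(dir, donor$donor_id)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  ann <- data.frame(sample_id = donor$samples$sample_id,
                    mni_x = donor$samples$x, mni_y = donor$samples$y,
                    mni_z = donor$samples$z,
                    hemisphere = donor$samples$hemisphere)
  utils::write.csv(ann, file.path(d, "SampleAnnot.csv"), row.names = FALSE,
                   quote = FALSE)
  expr <- data.frame(probe_id = rownames(donor$probe_expression),
                     donor$probe_expression, check.names = FALSE)
  utils::write.csv(expr, file.path(d, "MicroarrayExpression.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(donor$probes, file.path(d, "Probes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' Read an AHBA-dialect donor directory
#' @param dir a donor directory written by [write_donor_csv()].
#' @return a donor sample set list.
#' @export
read_donor_csv <- function(dir) {
  ann <- utils::read.csv(file.path(dir, "SampleAnnot.csv"),
                         stringsAsFactors = FALSE)
  expr <- utils::read.csv(file.path(dir, "MicroarrayExpression.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  probes <- utils::read.csv(file.path(dir, "Probes.csv"),
                            stringsAsFactors = FALSE)
  pe <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(pe) <- expr$probe_id
  list(donor_id = basename(dir),
       samples = data.frame(sample_id = ann$sample_id, x = ann$mni_x,
                            y = ann$mni_y, z = ann$mni_z,
                            hemisphere = ann$hemisphere,
                            stringsAsFactors = FALSE),
       probe_expression = pe, probes = probes)
}

#' Write / read an expression matrix as TSV (+ covered-mask sidecar)
#' @param x an `expression_matrix`.
#' @param path TSV path; the mask goes to `<path>.mask`.
#' @return `read_expression_matrix` returns an `expression_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(parcel_id = x$parcel_ids, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mask <- data.frame(parcel_id = names(x$covered_mask),
                     covered = as.integer(x$covered_mask))
  utils::write.table(mask, paste0(path, ".mask"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$parcel_id
  mask <- utils::read.delim(paste0(path, ".mask"), stringsAsFactors = FALSE)
  structure(list(values = vals, parcel_ids = df$parcel_id,
                 gene_ids = colnames(vals),
                 covered_mask = stats::setNames(mask$covered == 1L,
                                                mask$parcel_id),
                 flat_genes = character()),
            class = "expression_matrix")
}

#' Write / read a connectivity dataset as feature + metadata TSVs
#' @param dataset a `connectivity_dataset`.
#' @param prefix path prefix; writes `<prefix>_features.tsv`,
#'   `<prefix>_meta.tsv` and `<prefix>_featureinfo.tsv`.
#' @return `read_connectivity` returns a `connectivity_dataset`.
#' @export
write_connectivity <- function(dataset, prefix) {
  feats <- data.frame(subject_id = dataset$meta$subject_id,
                      dataset$features, check.names = FALSE)
  utils::write.table(feats, paste0(prefix, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$meta, paste0(prefix, "_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$feature_info, paste0(prefix, "_featureinfo.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(prefix) {
  feats <- utils::read.delim(paste0(prefix, "_features.tsv"),
                             check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(paste0(prefix, "_meta.tsv"),
                            stringsAsFactors = FALSE)
  fi <- utils::read.delim(paste0(prefix, "_featureinfo.tsv"),
                          stringsAsFactors = FALSE)
  new_connectivity_dataset(as.matrix(feats[, -1L, drop = FALSE]), meta, fi)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param sets named list of gene-id vectors.
#' @param path GMT path.
#' @return `read_gmt` returns a named list of member vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  sets
}

#' Write / read a genotype matrix as TSV ({0,1,2}, NA for missing)
#' @param genotypes subjects x SNP integer matrix.
#' @param path TSV path.
#' @return `read_genotypes` returns the integer matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df$subject_id
  g
}

#' Write a ranked gene list as TSV
#' @param ranked a `ranked_gene_list`.
#' @param path TSV path.
#' @return `read_ranked_genes` returns the data frame.
#' @export
write_ranked_genes <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_genes
#' @export
read_ranked_genes <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Write a truth record (or any plain list) as JSON
#' @param truth list to serialize.
#' @param path JSON path.
#' @return `read_truth` returns the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
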