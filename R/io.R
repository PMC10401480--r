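## Plain-text interfaces.  All tables are TSV; writers prepend a
## commented metadata header (`# key: value`) so outputs are diff-able
## and self-describing; readers skip `#` lines.

#' Read a count matrix
#'
#' TSV with first column `feature_id` and one column per sample
#' (integer cells), or a MatrixMarket `.mtx` triplet file with sidecar
#' ID files `<path>.features` and `<path>.samples` (one ID per line).
#'
#' @param path file path (`.mtx` selects the MatrixMarket route).
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    feat <- readLines(paste0(path, ".features"))
    samp <- readLines(paste0(path, ".samples"))
    dimnames(m) <- list(feat, samp)
    return(assert_count_matrix(m))
  }
  tab <- utils::read.delim(path, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "feature_id")
    stop("count matrix must have 'feature_id' as its first column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$feature_id
  storage.mode(m) <- "double"
  assert_count_matrix(m)
}

#' Read a feature-length table (`feature_id<TAB>length_bp`)
#' @param path two-column TSV.
#' @return named numeric vector of lengths.
#' @export
read_lengths <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("feature_id", "length_bp") %in% colnames(tab)))
    stop("lengths table needs columns feature_id, length_bp")
  stats::setNames(as.numeric(tab$length_bp), tab$feature_id)
}

#' Read a cohort design (`sample_id<TAB>group`)
#' @param path two-column TSV.
#' @return named character vector, sample_id -> group.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("design table needs columns sample_id, group")
  assert_design(stats::setNames(tab$group, tab$sample_id))
}

#' Read a feature x tissue median matrix
#' @param path TSV, first column `feature_id`, one column per tissue.
#' @return numeric matrix.
#' @export
read_tissue_medians <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Run metadata block
#'
#' Everything needed to reproduce a run byte-identically: package
#' version, timestamp, resolved configuration, input checksums and
#' seed.
#'
#' @param config named list (e.g. a `cascade_config`).
#' @param seed integer seed used for any randomness (or NA).
#' @param inputs named character vector of input file paths to
#'   checksum (md5).
#' @return named list.
#' @export
run_metadata <- function(config = list(), seed = NA, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "surfnom",
       version = as.character(utils::packageVersion("surfnom")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed,
       config = lapply(unclass(config), unclass),
       input_md5 = sums)
}

metadata_header <- function(meta) {
  if (is.null(meta)) return(character())
  paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
}

#' Write a table as TSV with a commented metadata header
#' @param tab data.frame.
#' @param path output path.
#' @param meta optional metadata list from [run_metadata()].
#' @export
write_tsv <- function(tab, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(metadata_header(meta), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame (metadata lines skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

matrix_to_tab <- function(m, id_col = "feature_id") {
  cbind(stats::setNames(data.frame(rownames(m),
                                   stringsAsFactors = FALSE), id_col),
        as.data.frame(m, check.names = FALSE))
}

#' Write all inputs of a simulated cohort to a directory
#'
#' Emits the files the cascade's readers consume: `counts.tsv`,
#' `lengths.tsv`, `design.tsv`, `gtex_medians.tsv`, the annotation
#' files (`cd_genes.txt`, `cspa_genes.txt`, `go_associations.tsv`),
#' the transcript-level bundle (`tx_*.tsv`, `tx2gene.tsv`), the truth
#' tables and `run_metadata.yaml`.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(matrix_to_tab(cohort$counts), p("counts.tsv"))
  write_tsv(data.frame(feature_id = names(cohort$lengths),
                       length_bp = unname(cohort$lengths)),
            p("lengths.tsv"))
  write_tsv(data.frame(sample_id = names(cohort$design),
                       group = unname(cohort$design)),
            p("design.tsv"))
  write_tsv(matrix_to_tab(cohort$tissue_medians), p("gtex_medians.tsv"))
  writeLines(cohort$sources[["CD"]]$genes, p("cd_genes.txt"))
  writeLines(cohort$sources[["CSPA"]]$genes, p("cspa_genes.txt"))
  utils::write.table(cohort$go_table, p("go_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_tsv(cohort$truth, p("truth.tsv"))
  iso <- cohort$isoforms
  write_tsv(matrix_to_tab(iso$counts), p("tx_counts.tsv"))
  write_tsv(data.frame(feature_id = names(iso$lengths),
                       length_bp = unname(iso$lengths)),
            p("tx_lengths.tsv"))
  write_tsv(data.frame(transcript_id = names(iso$tx2gene),
                       gene_id = unname(iso$tx2gene)),
            p("tx2gene.tsv"))
  write_tsv(matrix_to_tab(iso$medians), p("tx_gtex_medians.tsv"))
  write_tsv(iso$truth, p("tx_truth.tsv"))
  meta <- run_metadata(config = unclass(cohort$config),
                       seed = cohort$config$seed)
  writeLines(yaml::as.yaml(meta), p("run_metadata.yaml"))
  invisible(dir)
}
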