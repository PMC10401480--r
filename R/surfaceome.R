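## Surface-protein feature universe: annotation sources and catalog.
##
## Sources emulate the field's usual inputs: CD-nomenclature gene lists
## (HCDM), the mass-spectrometry-derived Cell Surface Protein Atlas, and
## pre-propagated GO annotations for ion transmembrane transport
## (GO:0034220), transmembrane transport (GO:0055085) and membrane
## (GO:0016020).  Identifiers are matched verbatim: no case folding and
## no alias resolution.

#' Load a plain-text gene list as an annotation source
#'
#' One identifier per line; `#` starts a comment (whole-line or
#' trailing); surrounding whitespace is stripped; duplicates removed;
#' case preserved.
#'
#' @param path file path.
#' @param source_id identifier for the source (default: file base name
#'   without extension).
#' @return object of class `annotation_source`: list with `source_id`
#'   and `genes` (character vector).
#' @export
load_gene_list <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("cannot read gene list: ", path)
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- unique(trimws(lines))
  genes <- genes[nzchar(genes)]
  if (!length(genes))
    warning("gene list '", source_id, "' is empty")
  annotation_source(source_id, genes)
}

#' Construct an annotation source from memory
#' @param source_id source identifier.
#' @param genes character vector of gene identifiers (deduplicated).
#' @return object of class `annotation_source`.
#' @export
annotation_source <- function(source_id, genes) {
  structure(list(source_id = source_id,
                 genes = unique(as.character(genes))),
            class = "annotation_source")
}

#' @export
print.annotation_source <- function(x, ...) {
  cat("<annotation_source>", x$source_id, "-",
      length(x$genes), "genes\n")
  invisible(x)
}

#' Load GO term memberships from a flat association table
#'
#' Reads a two-column TSV (`gene_id<TAB>go_id`, header optional) of
#' pre-propagated annotations and returns one annotation source per
#' requested term.  No ontology traversal is performed; propagation up
#' the GO graph is the caller's responsibility.
#'
#' @param path association TSV.
#' @param terms character vector of GO IDs to extract.
#' @return named list of `annotation_source`, one per term.  A term
#'   absent from the file yields an empty source with a warning.
#' @export
load_go_associations <- function(path, terms) {
  if (!file.exists(path)) stop("cannot read GO associations: ", path)
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("gene_id", "go_id"),
                           colClasses = "character")
  if (nrow(tab) && tab$gene_id[1] == "gene_id" && tab$go_id[1] == "go_id")
    tab <- tab[-1, , drop = FALSE]
  out <- lapply(terms, function(term) {
    genes <- tab$gene_id[tab$go_id == term]
    if (!length(genes))
      warning("GO term ", term, " not found in ", path)
    annotation_source(term, genes)
  })
  stats::setNames(out, terms)
}

#' Build the surface-protein catalog from annotation sources
#'
#' The catalog is the exact union of the member sets, with per-gene
#' provenance recording which sources support each gene.  Membership in
#' any one source suffices.
#'
#' @param sources list of `annotation_source` objects.
#' @return object of class `surface_catalog`: named list mapping
#'   gene_id to a character vector of supporting source IDs.
#' @export
build_catalog <- function(sources) {
  if (!length(sources)) stop("need at least one annotation source")
  for (src in sources) stopifnot(inherits(src, "annotation_source"))
  gene_vec <- unlist(lapply(sources, `[[`, "genes"), use.names = FALSE)
  src_vec <- rep(vapply(sources, `[[`, character(1), "source_id"),
                 vapply(sources, function(s) length(s$genes), integer(1)))
  if (!length(gene_vec))
    return(structure(list(), class = "surface_catalog"))
  prov <- lapply(split(src_vec, gene_vec), unique)
  structure(prov, class = "surface_catalog")
}

#' @export
print.surface_catalog <- function(x, ...) {
  srcs <- sort(unique(unlist(unclass(x))))
  cat("<surface_catalog>", length(x), "genes from",
      length(srcs), "sources:", paste(srcs, collapse = ", "), "\n")
  invisible(x)
}

#' Genes in a surface catalog
#' @param catalog a `surface_catalog`.
#' @return character vector of member gene IDs.
#' @export
catalog_genes <- function(catalog) names(catalog)

#' Membership query with verbatim identifier matching
#' @param catalog a `surface_catalog`.
#' @param ids character vector of gene identifiers.
#' @return logical vector, one entry per id.
#' @export
in_catalog <- function(catalog, ids) ids %in% names(catalog)

#' Collapse per-gene provenance to a display string
#' @param catalog a `surface_catalog`.
#' @param ids gene identifiers (default: all members).
#' @return character vector like `"CD;GO:0016020"`; `""` for
#'   non-members.
#' @export
catalog_provenance <- function(catalog, ids = catalog_genes(catalog)) {
  vapply(ids, function(g) {
    src <- catalog[[g]]
    if (is.null(src)) "" else paste(sort(src), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}
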