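#' Named gene set
#'
#' Gene symbols are stored uppercased so mouse-cased symbols (`Vim`) and
#' human symbols (`VIM`) hit the same sets; no ortholog mapping beyond
#' casing is attempted.
#'
#' @param name set name.
#' @param genes character vector of gene symbols; deduplicated after
#'   uppercasing.
#' @return An object of class `gene_set`: list with `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`. The
#' description field is discarded and symbols are uppercased.
#'
#' @param path path to a GMT file.
#' @return Named list of [gene_set] objects in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has ", length(fields),
           " fields; need name, description and at least one gene")
    gene_set(fields[1], fields[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove from a signature the genes it shares with another set
#'
#' Used for the overlap-robustness rerun: scoring is repeated after dropping
#' the genes an EMT signature shares with the SCLC subtype signature, to
#' check that the inferred E/M placement is not driven by shared genes.
#'
#' @param signature a [gene_set] to prune.
#' @param other the [gene_set] whose intersection with `signature` is removed.
#' @return A [gene_set] named `<signature>_excl` with the intersection removed.
#' @export
exclude_overlap <- function(signature, other) {
  stopifnot(inherits(signature, "gene_set"), inherits(other, "gene_set"))
  shared <- intersect(signature$genes, other$genes)
  kept <- setdiff(signature$genes, other$genes)
  if (!length(kept))
    stop("excluding overlap with '", other$name, "' empties gene set '",
         signature$name, "'")
  if (length(shared))
    message("exclude_overlap: removed ", length(shared), " genes from '",
            signature$name, "': ", paste(shared, collapse = ", "))
  gene_set(paste0(signature$name, "_excl"), kept)
}

#' Jaccard index of two gene sets
#'
#' @param a,b non-empty [gene_set] objects.
#' @return `|a intersect b| / |a union b|`, in `[0, 1]`.
#' @examples
#' jaccard_index(gene_set("x", c("A", "B")), gene_set("y", c("B", "C")))
#' @export
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  length(intersect(a$genes, b$genes)) / length(union(a$genes, b$genes))
}
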