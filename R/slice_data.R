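#' Construct a slice_data object
#'
#' A `slice_data` holds one spatially resolved transcriptomics (SRT) slice:
#' spot coordinates, a spots-by-genes expression matrix, identifier vectors,
#' and an optional per-spot domain annotation.
#'
#' @param coords numeric matrix, n x 2, spot coordinates (platform units).
#' @param expr numeric matrix, n x p, expression (raw counts or preprocessed).
#' @param gene_ids character vector of length p; defaults to `colnames(expr)`
#'   or `gene1..geneP`.
#' @param spot_ids character vector of length n; defaults to `rownames(expr)`
#'   or `spot1..spotN`.
#' @param labels optional length-n factor (or coercible) of domain annotations.
#'
#' @return An object of class `slice_data` with elements `coords`, `expr`,
#'   `gene_ids`, `spot_ids`, `labels`, `n`, `p`.
#' @export
slice_data <- function(coords, expr, gene_ids = NULL, spot_ids = NULL,
                       labels = NULL) {
  coords <- as.matrix(coords)
  expr <- as.matrix(expr)
  if (ncol(coords) != 2L)
    stop("`coords` must have exactly 2 columns")
  if (nrow(coords) != nrow(expr))
    stop("`coords` and `expr` disagree on the number of spots (",
         nrow(coords), " vs ", nrow(expr), ")")
  if (nrow(expr) < 1L || ncol(expr) < 1L)
    stop("need at least one spot and one gene")
  if (!all(is.finite(coords)))
    stop("`coords` contains non-finite values")
  if (!all(is.finite(expr)))
    stop("`expr` contains non-finite values")
  if (is.null(gene_ids)) gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expr)))
  if (is.null(spot_ids)) spot_ids <- rownames(expr)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(expr)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != ncol(expr))
    stop("`gene_ids` length does not match the gene dimension of `expr`")
  if (length(spot_ids) != nrow(expr))
    stop("`spot_ids` length does not match the spot dimension of `expr`")
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != nrow(expr))
      stop("`labels` length does not match the number of spots")
  }
  dimnames(expr) <- list(spot_ids, gene_ids)
  dimnames(coords) <- list(spot_ids, c("x", "y"))
  structure(
    list(coords = coords, expr = expr, gene_ids = gene_ids,
         spot_ids = spot_ids, labels = labels,
         n = nrow(expr), p = ncol(expr)),
    class = "slice_data"
  )
}

#' @export
print.slice_data <- function(x, ...) {
  cat("slice_data:", x$n, "spots x", x$p, "genes",
      if (!is.null(x$labels))
        paste0("(", nlevels(x$labels), " annotated domains)") else "",
      "\n")
  invisible(x)
}

#' Read one SRT slice from disk
#'
#' Two on-disk layouts are supported. `csv_mtx` is a plain-text bundle
#' directory containing `matrix.mtx` (genes x spots, Matrix Market),
#' `genes.tsv`, `barcodes.tsv`, `coords.csv` (columns `barcode,x,y`) and an
#' optional `labels.tsv` (columns `barcode,label`). `h5ad` reads an AnnData
#' container (expression in `X`, coordinates in `obsm["spatial"]`) through a
#' bundled Python bridge, which requires a `python` with `anndata` on the
#' PATH.
#'
#' @param path file (h5ad) or bundle directory (csv_mtx).
#' @param format `"csv_mtx"` or `"h5ad"`; default guesses from the path.
#' @return A [slice_data] with raw values in `expr`, spot order as on disk.
#' @export
read_slice <- function(path, format = c("auto", "csv_mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else "csv_mtx"
  if (format == "h5ad") {
    tmp <- tempfile("h5ad_bundle_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    h5ad_bridge("to_bundle", path, tmp)
    return(read_slice(tmp, "csv_mtx"))
  }
  need <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "coords.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("csv_mtx bundle at '", path, "' is missing: ",
         paste(basename(missing), collapse = ", "))
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))   # genes x spots
  genes <- readLines(file.path(path, "genes.tsv"))
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  co <- utils::read.csv(file.path(path, "coords.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(co)))
    stop("coords.csv must have columns barcode, x, y")
  if (nrow(m) != length(genes))
    stop("matrix.mtx gene dimension (", nrow(m),
         ") does not match genes.tsv (", length(genes), ")")
  if (ncol(m) != length(barcodes))
    stop("matrix.mtx spot dimension (", ncol(m),
         ") does not match barcodes.tsv (", length(barcodes), ")")
  if (nrow(co) != length(barcodes))
    stop("coords.csv has ", nrow(co), " rows but barcodes.tsv lists ",
         length(barcodes), " spots")
  co <- co[match(barcodes, co$barcode), , drop = FALSE]
  if (anyNA(co$barcode))
    stop("coords.csv barcodes do not cover all of barcodes.tsv")
  labels <- NULL
  labf <- file.path(path, "labels.tsv")
  if (file.exists(labf)) {
    lab <- utils::read.delim(labf, stringsAsFactors = FALSE)
    labels <- lab$label[match(barcodes, lab$barcode)]
  }
  slice_data(coords = cbind(x = co$x, y = co$y),
             expr = t(as.matrix(m)),
             gene_ids = genes, spot_ids = barcodes, labels = labels)
}

#' Write one SRT slice to disk
#'
#' Inverse of [read_slice]; see there for the on-disk layouts.
#'
#' @param x a [slice_data].
#' @param path output bundle directory (csv_mtx) or `.h5ad` file path.
#' @param format `"csv_mtx"` or `"h5ad"`; default guesses from the path.
#' @return `path`, invisibly.
#' @export
write_slice <- function(x, path, format = c("auto", "csv_mtx", "h5ad")) {
  stopifnot(inherits(x, "slice_data"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else "csv_mtx"
  if (format == "h5ad") {
    tmp <- tempfile("h5ad_bundle_")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    write_slice(x, tmp, "csv_mtx")
    h5ad_bridge("from_bundle", tmp, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(t(x$expr)),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(path, "genes.tsv"))
  writeLines(x$spot_ids, file.path(path, "barcodes.tsv"))
  utils::write.csv(
    data.frame(barcode = x$spot_ids, x = x$coords[, 1], y = x$coords[, 2]),
    file.path(path, "coords.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(x$labels))
    utils::write.table(
      data.frame(barcode = x$spot_ids, label = as.character(x$labels)),
      file.path(path, "labels.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  invisible(path)
}

# Run the bundled anndata conversion script; `mode` is to_bundle/from_bundle.
h5ad_bridge <- function(mode, src, dst) {
  script <- system.file("python", "h5ad_bridge.py", package = "jade")
  if (!nzchar(script))
    script <- file.path("inst", "python", "h5ad_bridge.py")  # dev tree
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("h5ad support needs a `python` with anndata on the PATH")
  st <- system2(py, c(script, mode, shQuote(src), shQuote(dst)),
                stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status")
  if (!is.null(code) && code != 0)
    stop("h5ad bridge failed: ", paste(st, collapse = "\n"))
  invisible(NULL)
}

#' Write a transport plan and its argmax matches to disk
#'
#' Writes `plan.mtx` (sparse Matrix Market, entries below `floor` dropped),
#' `rows.tsv` / `cols.tsv` (the two slices' barcodes) and `pairs.tsv`, the
#' per-row argmax match table with the transported mass.
#'
#' @param plan a [transport_plan] (or plain matrix).
#' @param ids_a,ids_b barcode vectors for the two slices.
#' @param path output directory.
#' @param floor entries strictly below this are not stored (default 0 keeps
#'   everything nonzero).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(plan, ids_a, ids_b, path, floor = 0) {
  pi_m <- plan_matrix(plan)
  if (nrow(pi_m) != length(ids_a) || ncol(pi_m) != length(ids_b))
    stop("plan dimensions (", nrow(pi_m), "x", ncol(pi_m),
         ") do not match identifier lists (", length(ids_a), ", ",
         length(ids_b), ")")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  keep <- pi_m
  keep[keep < floor] <- 0
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(keep, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(path, "plan.mtx"))
  writeLines(as.character(ids_a), file.path(path, "rows.tsv"))
  writeLines(as.character(ids_b), file.path(path, "cols.tsv"))
  j <- apply(pi_m, 1L, which.max)
  utils::write.table(
    data.frame(row_barcode = ids_a, col_barcode = ids_b[j],
               mass = pi_m[cbind(seq_along(j), j)]),
    file.path(path, "pairs.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Read back a transport plan written by [write_alignment]
#'
#' @param path directory written by [write_alignment].
#' @return list with `pi` (dense matrix with barcode dimnames), `ids_a`,
#'   `ids_b`.
#' @export
read_alignment <- function(path) {
  pi_m <- as.matrix(Matrix::readMM(file.path(path, "plan.mtx")))
  ids_a <- readLines(file.path(path, "rows.tsv"))
  ids_b <- readLines(file.path(path, "cols.tsv"))
  dimnames(pi_m) <- list(ids_a, ids_b)
  list(pi = pi_m, ids_a = ids_a, ids_b = ids_b)
}
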