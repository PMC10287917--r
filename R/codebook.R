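#' Binary barcode codebook
#'
#' The codebook assigns each of `G` genes an `F`-bit binary barcode: gene `g`
#' fluoresces in imaging round `f` iff `barcodes[g, f] == 1`. "Blank" barcodes
#' are codewords assigned to no gene; any transcript decoded to a blank is a
#' false positive by construction, which downstream adaptive filtering
#' exploits.
#'
#' @param gene_names Character vector of `G` identifiers.
#' @param barcodes `G x F` matrix over \{0, 1\}.
#' @param is_blank Logical vector of length `G`.
#' @param bit_order Integer permutation mapping image page `f` to barcode
#'   column; defaults to identity.
#' @return A `codebook` object.
#' @examples
#' cb <- codebook(c("Rorb", "Blank-1"),
#'                rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)),
#'                is_blank = c(FALSE, TRUE))
#' n_bits(cb)
#' @export
codebook <- function(gene_names, barcodes, is_blank = NULL, bit_order = NULL) {
  barcodes <- as.matrix(barcodes)
  storage.mode(barcodes) <- "double"
  G <- nrow(barcodes)
  if (length(gene_names) != G) {
    stop("`gene_names` length must equal nrow(barcodes)")
  }
  if (is.null(is_blank)) is_blank <- grepl("^Blank-", gene_names)
  if (length(is_blank) != G) stop("`is_blank` length must equal nrow(barcodes)")
  if (!all(barcodes %in% c(0, 1))) stop("barcode entries must be 0 or 1")
  if (anyDuplicated(apply(barcodes, 1, paste, collapse = ""))) {
    stop("barcodes must be pairwise distinct")
  }
  if (all(is_blank)) stop("codebook needs at least one non-blank barcode")
  if (is.null(bit_order)) bit_order <- seq_len(ncol(barcodes))
  if (!identical(sort(as.integer(bit_order)), seq_len(ncol(barcodes)))) {
    stop("`bit_order` must be a permutation of 1..F")
  }
  rownames(barcodes) <- gene_names
  structure(
    list(
      gene_names = as.character(gene_names),
      barcodes = barcodes,
      is_blank = as.logical(is_blank),
      bit_order = as.integer(bit_order)
    ),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "<codebook> %d genes (%d blank), %d bits\n",
    n_genes(x), sum(x$is_blank), n_bits(x)
  ))
  invisible(x)
}

#' Number of genes (codebook rows, including blanks)
#' @param cb A `codebook`.
#' @export
n_genes <- function(cb) nrow(cb$barcodes)

#' Number of barcode bits (imaging rounds)
#' @param cb A `codebook`.
#' @export
n_bits <- function(cb) ncol(cb$barcodes)

#' Codebook matrix C with columns in image-page order
#'
#' Returns the `G x F` matrix whose column `f` corresponds to image page `f`
#' (applying `bit_order`). This is the matrix that enters the forward model.
#' @param cb A `codebook`.
#' @export
codebook_matrix <- function(cb) {
  unname(cb$barcodes[, cb$bit_order, drop = FALSE])
}

#' Read a codebook from CSV
#'
#' Expects columns `gene,barcode,is_blank` where `barcode` is an F-character
#' string over 0/1 (e.g. `Rorb,0110100010,0`).
#' @param path CSV file path.
#' @return A `codebook`.
#' @export
read_codebook <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    gene = "character", barcode = "character"
  ))
  need <- c("gene", "barcode", "is_blank")
  if (!all(need %in% names(df))) {
    stop("codebook CSV must have columns gene, barcode, is_blank")
  }
  widths <- nchar(df$barcode)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("codebook line %d: barcode width %d != %d",
                 bad + 1L, widths[bad], widths[1]))
  }
  if (any(grepl("[^01]", df$barcode))) {
    bad <- which(grepl("[^01]", df$barcode))[1]
    stop(sprintf("codebook line %d: barcode contains non-binary characters",
                 bad + 1L))
  }
  bits <- do.call(rbind, lapply(strsplit(df$barcode, ""), as.numeric))
  codebook(df$gene, bits, is_blank = as.logical(as.integer(df$is_blank)))
}

#' Write a codebook to CSV
#' @param cb A `codebook`.
#' @param path Output CSV file path.
#' @export
write_codebook <- function(cb, path) {
  df <- data.frame(
    gene = cb$gene_names,
    barcode = apply(cb$barcodes, 1, function(b) paste(as.integer(b), collapse = "")),
    is_blank = as.integer(cb$is_blank)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
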