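`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv0 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a relationship matrix for inspection
#'
#' Dense matrices are written as a labelled TSV; sparse matrices as a
#' coordinate-triplet TSV (`row`, `col`, `value` with labels).
#'
#' @param m matrix or Matrix (typically a `relationship_matrix`).
#' @param path output file.
#' @param sparse write triplets instead of a dense table.
#' @return `path`, invisibly.
#' @export
export_matrix_tsv <- function(m, path, sparse = is(m, "sparseMatrix")) {
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (sparse) {
    tm <- as(as(m, "CsparseMatrix"), "TsparseMatrix")
    df <- data.frame(row = labels[tm@i + 1L], col = labels[tm@j + 1L],
                     value = tm@x)
    write_tsv0(df[order(df$row, df$col), ], path)
  } else {
    dm <- as.data.frame(as.matrix(m))
    names(dm) <- labels
    write_tsv0(cbind(id = labels, dm), path)
  }
}

new_relationship_matrix <- function(values, labels, kind) {
  dimnames(values) <- list(labels, labels)
  attr(values, "kind") <- kind
  # S4 Matrix objects carry the kind as a plain attribute; dense base
  # matrices additionally get an S3 class for printing.
  if (is.matrix(values))
    class(values) <- c("relationship_matrix", class(values))
  values
}

#' @method print relationship_matrix
#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship matrix, kind = %s, %d x %d>\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

rel_kind <- function(x) attr(x, "kind")
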