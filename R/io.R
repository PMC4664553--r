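#' Read a genes-by-samples expression table
#'
#' Tab-delimited text with gene identifiers in the first column and sample
#' identifiers in the header row.  Validation is strict: duplicate gene
#' identifiers, missing values and non-numeric cells are errors that name
#' the offending rows/cells.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 4L) stop("expected gene ids plus at least 3 sample columns")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    loc <- apply(utils::head(bad, 5L), 1L, function(z)
      sprintf("gene %s, sample %s", ids[z[1L]], colnames(vals)[z[2L]]))
    stop("non-numeric or missing cells at: ", paste(loc, collapse = "; "))
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write an expression matrix as tab-delimited text
#' @param expr numeric matrix with dimnames.
#' @param path file path.
#' @export
write_expression <- function(expr, path) {
  # full double precision so write/read round-trips are exact
  chr <- matrix(sprintf("%.17g", expr), nrow = nrow(expr),
                dimnames = dimnames(expr))
  df <- data.frame(gene = rownames(expr), chr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples-by-traits table
#'
#' Tab-delimited with a `sample` column; remaining columns are traits
#' (numeric or categorical).
#' @param path file path.
#' @return data frame with samples as rownames.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"sample" %in% names(df)) stop("trait table needs a `sample` column")
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in trait table")
  rownames(df) <- df$sample
  df[, setdiff(names(df), "sample"), drop = FALSE]
}

#' Read a survival table (`sample`, `time`, `event`)
#' @param path file path.
#' @return validated data frame.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  if (any(df$time < 0)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1))) stop("event must be coded 0/1")
  df[, need]
}

#' Write a network as a weighted edge list (TSV)
#' @param network weighted `igraph`.
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  write.table(data.frame(node1 = el[, 1L], node2 = el[, 2L], weight = w),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list (TSV) into an igraph network
#' @param path file path with columns `node1`, `node2`, `weight`.
#' @return weighted `igraph`.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("node1", "node2") %in% names(df)))
  if (!"weight" %in% names(df)) df$weight <- 1
  igraph::graph_from_data_frame(df[, c("node1", "node2", "weight")],
                                directed = FALSE)
}

#' Write a network in GML format
#' @param network `igraph`.
#' @param path file path.
#' @export
write_gml <- function(network, path) {
  igraph::write_graph(network, path, format = "gml")
  invisible(path)
}
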