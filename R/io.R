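# Delimited-text input/output. All files are tab-delimited unless noted.

#' Read a marker dosage matrix
#'
#' Expects a tab-delimited text file: first column marker id, header row of
#' individual ids, entries integer dosages or the missing-value string.
#'
#' @param path File path.
#' @param na Missing-value string (default `"NA"`).
#' @return Integer matrix markers x individuals.
#' @export
read_dosage_matrix <- function(path, na = "NA") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = na, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname read_dosage_matrix
#' @param dosages Matrix to write.
#' @export
write_dosage_matrix <- function(dosages, path, na = "NA") {
  df <- data.frame(marker = rownames(dosages), dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = na)
  invisible(path)
}

#' Read a haploblock definition
#'
#' Two-column tab-delimited file (`block`, `marker`); marker order within
#' a block follows file order.
#'
#' @param path File path.
#' @return Named list block -> character vector of markers.
#' @export
read_haploblocks <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  as_block_list(df)
}

#' Read a full-sib family specification
#'
#' One line per family: family id, parent1, parent2, then offspring ids,
#' tab-separated, no header.
#'
#' @param path File path.
#' @return Tibble with columns `family`, `parent1`, `parent2` and
#'   list-column `offspring`.
#' @export
read_fs_families <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    family = vapply(parts, `[[`, character(1L), 1L),
    parent1 = vapply(parts, `[[`, character(1L), 2L),
    parent2 = vapply(parts, `[[`, character(1L), 3L),
    offspring = lapply(parts, function(p) p[-(1:3)]))
}

#' @rdname read_fs_families
#' @param families Tibble to write.
#' @export
write_fs_families <- function(families, path) {
  lines <- vapply(seq_len(nrow(families)), function(i) {
    paste(c(families$family[i], families$parent1[i], families$parent2[i],
            families$offspring[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pedigree
#'
#' Three-column tab-delimited file with header: `indiv`, `parent1`,
#' `parent2`; missing parent = `NA`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_pedigree <- function(path) {
  tibble::as_tibble(utils::read.delim(path, header = TRUE, sep = "\t",
                                      na.strings = "NA",
                                      colClasses = "character"))
}

#' Haplotype-dosage matrix of one block's assignments
#'
#' Converts the assignments of one block into the standard output form:
#' rows = haplotype codes observed in the block, columns = individuals,
#' entries = per-haplotype dosages summing to the ploidy for assigned
#' individuals and `NA` throughout for unassigned ones.
#'
#' @param result A `hap_result`.
#' @param block Block name.
#' @return Integer matrix.
#' @export
hap_dosage_matrix <- function(result, block) {
  sub <- result$assignments[result$assignments$block == block, ]
  if (nrow(sub) == 0L) stop("unknown block: ", block, call. = FALSE)
  codes <- sort(unique(unlist(sub$ghap)))
  m <- matrix(NA_integer_, nrow = length(codes), ncol = nrow(sub),
              dimnames = list(paste0("h", codes), sub$indiv))
  for (i in seq_len(nrow(sub))) {
    if (sub$assigned[i]) {
      m[, i] <- 0L
      tb <- table(sub$ghap[[i]])
      m[paste0("h", names(tb)), i] <- as.integer(tb)
    }
  }
  m
}
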