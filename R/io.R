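# Delimited-text serialization of scan matrices and profiles. Every file
# embeds the full parameter set and seed needed to regenerate it.

meta_header <- function(meta) {
  kv <- vapply(names(meta), function(k)
    paste0(k, "=", format(meta[[k]], digits = 17)), character(1L))
  paste0("# ", paste(kv, collapse = " "))
}

#' Write a scan matrix as TSV
#'
#' Tab-separated matrix with site-id row/column headers, preceded by a
#' commented metadata line (method, sigma, k, kBT, R0, M, seed).
#'
#' @param x a `scan_matrix`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_scan_matrix <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(scan_meta(x)), con)
  writeLines(paste(c("site_id", colnames(x)), collapse = "\t"), con)
  m <- unclass(x)
  body <- apply(cbind(rownames(m), format(m, digits = 17, trim = TRUE,
                                          scientific = FALSE)),
                1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a scan matrix written by [write_scan_matrix()]
#'
#' @param path TSV path.
#' @return A `scan_matrix` with metadata restored.
#' @export
read_scan_matrix <- function(path) {
  lines <- readLines(path)
  meta_line <- sub("^# ", "", lines[startsWith(lines, "#")][1L])
  kv <- strsplit(strsplit(meta_line, " ", fixed = TRUE)[[1L]], "=",
                 fixed = TRUE)
  meta <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(v) && p[2L] != "NA") p[2L] else v
  })
  names(meta) <- vapply(kv, `[[`, character(1L), 1L)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab)
  subclass <- if (identical(meta$method, "admrs") ||
                  identical(meta$method, "sdmrs")) {
    "compensation_matrix"
  } else {
    "sensitivity_matrix"
  }
  structure(m, meta = meta, class = c(subclass, "scan_matrix", class(m)))
}

#' Write marginal profiles as TSV
#'
#' One row per site: site id plus one column per profile.
#'
#' @param profiles a `marginal_profiles` list.
#' @param path output path.
#' @param site_ids optional site identifiers (defaults to profile names or
#'   indices).
#' @return The path, invisibly.
#' @export
write_profiles <- function(profiles, path, site_ids = NULL) {
  vals <- unclass(profiles)
  n <- length(vals[[1L]])
  ids <- site_ids %||% names(vals[[1L]]) %||% as.character(seq_len(n))
  df <- data.frame(site_id = ids, vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
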