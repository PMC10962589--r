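#' FEXI acquisition schemes
#'
#' A FEXI acquisition scheme is an ordered table of double diffusion-encoding
#' measurements. Each row holds the filter b-value `bf` (s/mm^2), the mixing
#' time `tm` (s), the encoding b-value `b` (s/mm^2), the filter and encoding
#' echo times `TEf` and `TE` (s), and `n_rep`, the number of acquired volumes
#' averaged into that row (gradient directions times signal averages; the
#' models assume isotropic, direction-averaged signals).
#'
#' All times are stored in seconds and b-values in s/mm^2. Diffusivities are
#' carried in um^2/ms throughout the package; the forward models apply the
#' factor 1e-3 so that `b * D` is dimensionless.
#'
#' @param bf,tm,b,TEf,TE,n_rep numeric vectors, recycled to a common length.
#' @param name free-text label for the scheme.
#' @return A `fexi_scheme`, a data frame with the columns above.
#' @examples
#' sch <- fexi_scheme(bf = c(0, 0), tm = 0.02, b = c(0, 250),
#'                    TEf = 0.038, TE = 0.062)
#' @export
fexi_scheme <- function(bf, tm, b, TEf, TE, n_rep = 1L, name = "scheme") {
  df <- data.frame(bf = as.numeric(bf), tm = as.numeric(tm),
                   b = as.numeric(b), TEf = as.numeric(TEf),
                   TE = as.numeric(TE), n_rep = as.integer(n_rep))
  validate_scheme(df)
  structure(df, name = name, class = c("fexi_scheme", "data.frame"))
}

validate_scheme <- function(df) {
  required <- c("bf", "tm", "b", "TEf", "TE", "n_rep")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("scheme is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("scheme must contain at least one measurement")
  with(df, {
    if (any(!is.finite(bf)) || any(bf < 0)) stop("bf must be finite and >= 0")
    if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and >= 0")
    if (any(!is.finite(tm)) || any(tm <= 0)) stop("tm must be finite and > 0")
    if (any(!is.finite(TEf)) || any(TEf <= 0)) stop("TEf must be finite and > 0")
    if (any(!is.finite(TE)) || any(TE <= 0)) stop("TE must be finite and > 0")
    if (any(is.na(n_rep)) || any(n_rep < 1L)) stop("n_rep must be >= 1")
  })
  invisible(df)
}

#' @export
print.fexi_scheme <- function(x, ...) {
  cat("FEXI acquisition scheme '", attr(x, "name"), "': ", nrow(x),
      " measurements, ", nominal_volumes(x), " nominal volumes\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Total number of acquired volumes represented by a scheme
#'
#' @param scheme a [fexi_scheme()].
#' @return Integer: `sum(n_rep)`.
#' @export
nominal_volumes <- function(scheme) sum(scheme$n_rep)

#' Group index of each measurement by filter block
#'
#' Measurements sharing a (bf, tm) pair form a normalization group: each
#' group's encoding b = 0 signal is the reference that the group is divided by.
#'
#' @param scheme a [fexi_scheme()].
#' @return Integer vector of group ids, one per measurement.
#' @keywords internal
scheme_groups <- function(scheme) {
  as.integer(interaction(scheme$bf, scheme$tm, drop = TRUE, lex.order = TRUE))
}

#' Reference single-slice BBB-FEXI protocol
#'
#' The default protocol crosses four filter blocks, (bf, tm) in
#' \{(0, 20 ms), (250, 20 ms), (250, 200 ms), (250, `tm_max`)\}, with five
#' encoding b-values \{0, 50, 100, 250, 1000\} s/mm^2, at TEf = 38 ms and
#' TE = 62 ms. Each of the 20 measurements collapses 3 gradient directions
#' x 5 averages into `n_rep = 15`, for 300 nominal volumes.
#'
#' @param TEf,TE filter and encoding echo times (s).
#' @param tm_max longest mixing time (s).
#' @return A [fexi_scheme()] with 20 measurements.
#' @export
default_scheme <- function(TEf = 0.038, TE = 0.062, tm_max = 0.400) {
  blocks <- data.frame(bf = c(0, 250, 250, 250),
                       tm = c(0.020, 0.020, 0.200, tm_max))
  b <- c(0, 50, 100, 250, 1000)
  idx <- expand.grid(ib = seq_along(b), iblk = seq_len(nrow(blocks)))
  fexi_scheme(bf = blocks$bf[idx$iblk], tm = blocks$tm[idx$iblk],
              b = b[idx$ib], TEf = TEf, TE = TE, n_rep = 15L,
              name = "bbb-fexi full protocol")
}

#' Protocol subsets for the AXR and compartmental paradigms
#'
#' The AXR subset keeps only measurements with encoding b in \{0, 250\} s/mm^2
#' at their full repetition count; the compartmental subset keeps all
#' b-values at two repetitions (x3 directions, so `n_rep = 6`). Applied to
#' [default_scheme()] both contain 120 nominal volumes, matching each other
#' in acquisition time.
#'
#' @param scheme a [fexi_scheme()].
#' @param mode `"axr"` or `"compartmental"`.
#' @return A [fexi_scheme()]; always a sub-multiset of `scheme`'s rows.
#' @export
subset_scheme <- function(scheme, mode = c("axr", "compartmental")) {
  mode <- match.arg(mode)
  if (mode == "axr") {
    if (!all(c(0, 250) %in% scheme$b))
      stop("AXR subset requires encoding b-values 0 and 250 s/mm^2")
    out <- scheme[scheme$b %in% c(0, 250), , drop = FALSE]
  } else {
    out <- scheme
    out$n_rep <- pmin(out$n_rep, 6L)  # 2 repetitions x 3 directions
  }
  rownames(out) <- NULL
  structure(out, name = paste(attr(scheme, "name"), mode),
            class = c("fexi_scheme", "data.frame"))
}

#' Expand averaged measurements into single-repetition rows
#'
#' Each row is replicated `n_rep` times with `n_rep = 1`, turning the scheme
#' into one row per acquired volume (e.g. for generating replicate volumes of
#' a phantom, or for per-volume noise).
#'
#' @param scheme a [fexi_scheme()].
#' @return A [fexi_scheme()] with `nominal_volumes(scheme)` rows.
#' @export
expand_scheme <- function(scheme) {
  idx <- rep(seq_len(nrow(scheme)), scheme$n_rep)
  out <- scheme[idx, , drop = FALSE]
  out$n_rep <- 1L
  rownames(out) <- NULL
  structure(out, name = paste(attr(scheme, "name"), "(expanded)"),
            class = c("fexi_scheme", "data.frame"))
}

scheme_file_cols <- c(bf = "bf_s_per_mm2", tm = "tm_ms", b = "b_s_per_mm2",
                      TEf = "TEf_ms", TE = "TE_ms", n_rep = "n_rep")

#' Read and write scheme files
#'
#' Scheme files are comma- or tab-delimited text with a header line and
#' optional `#` comments. Columns: `bf_s_per_mm2, tm_ms, b_s_per_mm2, TEf_ms,
#' TE_ms, n_rep`; times are in milliseconds on disk and converted to seconds
#' in memory. Unknown columns are ignored with a warning. A copy of the
#' reference protocol ships as `system.file("extdata", "table1_scheme.csv",
#' package = "bbbfexi")`.
#'
#' @param path file path.
#' @return `read_scheme` returns a [fexi_scheme()]; `write_scheme` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("scheme file is empty: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          strip.white = TRUE, check.names = FALSE)
  missing <- setdiff(unname(scheme_file_cols), names(df))
  if (length(missing))
    stop("scheme file is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), unname(scheme_file_cols))
  if (length(extra))
    warning("ignoring unknown scheme column(s): ", paste(extra, collapse = ", "))
  for (col in scheme_file_cols)
    if (!is.numeric(df[[col]]) || any(is.na(df[[col]])))
      stop("non-numeric or missing values in scheme column ", col)
  fexi_scheme(bf = df$bf_s_per_mm2, tm = df$tm_ms / 1000,
              b = df$b_s_per_mm2, TEf = df$TEf_ms / 1000,
              TE = df$TE_ms / 1000, n_rep = df$n_rep,
              name = basename(path))
}

#' @rdname read_scheme
#' @param scheme a [fexi_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  df <- data.frame(scheme$bf, scheme$tm * 1000, scheme$b,
                   scheme$TEf * 1000, scheme$TE * 1000, scheme$n_rep)
  names(df) <- unname(scheme_file_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# FEXI acquisition scheme: ", attr(scheme, "name")), con)
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
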