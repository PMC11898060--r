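# PLUMED-style HILLS text records: deposited Gaussian bias terms.

#' Read a HILLS file
#'
#' Parses the PLUMED HILLS dialect: a `#! FIELDS ...` header naming the
#' columns, optional `#! SET ...` metadata lines (periodicity bounds are
#' captured), and whitespace-separated numeric rows.  Column order follows
#' the header.  Expected fields are `time`, one center column per
#' collective variable, matching `sigma_<cv>` width columns, `height`,
#' and optionally `biasf`.
#'
#' @param path file path (or a connection) to read.
#' @return a tibble with one row per deposited hill; attributes `cv_names`
#'   (character) and `periodic` (named list of `c(min, max)` or `NULL`)
#'   describe the collective variables.
#' @examples
#' h <- synthetic_hills_example()
#' f <- tempfile(); write_hills(h, f)
#' read_hills(f)
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  header <- grep("^#!", lines, value = TRUE)
  fields_line <- grep("^#!\\s*FIELDS", header, value = TRUE)
  if (length(fields_line) == 0) {
    abort("not a HILLS file: missing '#! FIELDS' header line")
  }
  cols <- strsplit(sub("^#!\\s*FIELDS\\s+", "", fields_line[1]), "\\s+")[[1]]

  sigma_cols <- grep("^sigma_", cols, value = TRUE)
  cv_names <- sub("^sigma_", "", sigma_cols)
  if (length(cv_names) == 0 || !all(cv_names %in% cols)) {
    abort("HILLS header must declare center and matching sigma_* columns")
  }
  if (!"height" %in% cols) abort("HILLS header is missing the 'height' column")

  periodic <- setNames(vector("list", length(cv_names)), cv_names)
  for (cv in cv_names) {
    mn <- .hills_set_value(header, paste0("min_", cv))
    mx <- .hills_set_value(header, paste0("max_", cv))
    if (!is.na(mn) && !is.na(mx)) periodic[[cv]] <- c(mn, mx)
  }

  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0) {
    dat <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  } else {
    mat <- matrix(scan(text = data_lines, quiet = TRUE),
                  ncol = length(cols), byrow = TRUE)
    dat <- as_tibble(setNames(as.data.frame(mat), cols))
  }
  if ("time" %in% cols && is.unsorted(dat$time)) {
    warn("HILLS time column is not non-decreasing")
  }
  if (any(dat$height < 0)) abort("HILLS heights must be non-negative")
  if (any(as.matrix(dat[sigma_cols]) <= 0)) abort("HILLS sigmas must be positive")
  attr(dat, "cv_names") <- cv_names
  attr(dat, "periodic") <- periodic
  dat
}

.hills_set_value <- function(header, key) {
  ln <- grep(paste0("^#!\\s*SET\\s+", key, "\\b"), header, value = TRUE)
  if (length(ln) == 0) return(NA_real_)
  val <- strsplit(trimws(ln[1]), "\\s+")[[1]][4]
  if (val == "pi") return(pi)
  if (val == "-pi") return(-pi)
  if (val == "2pi") return(2 * pi)
  suppressWarnings(as.numeric(val))
}

#' Write a HILLS file
#'
#' @param hills tibble of hills, as returned by [read_hills()] or
#'   [sample_wt_metad()]; collective-variable names are taken from the
#'   `cv_names` attribute or inferred from the `sigma_*` columns.
#' @param path output file path.
#' @param digits significant digits for the numeric table.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path, digits = 17) {
  cv_names <- attr(hills, "cv_names") %||%
    sub("^sigma_", "", grep("^sigma_", names(hills), value = TRUE))
  cols <- names(hills)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  periodic <- attr(hills, "periodic")
  for (cv in cv_names) {
    pr <- periodic[[cv]]
    if (!is.null(pr)) {
      writeLines(c(sprintf("#! SET min_%s %.17g", cv, pr[1]),
                   sprintf("#! SET max_%s %.17g", cv, pr[2])), con)
    }
  }
  mat <- format(as.data.frame(hills), digits = digits, scientific = TRUE,
                trim = TRUE)
  writeLines(do.call(paste, c(mat, sep = " ")), con)
  invisible(path)
}

#' Tiny in-memory HILLS example
#'
#' A 50-record synthetic hills series over a periodic `phi` and bounded
#' `theta` axis, used in examples and round-trip tests.
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @return hills tibble with `cv_names`/`periodic` attributes.
#' @export
synthetic_hills_example <- function(n = 50, seed = 1) {
  set.seed(seed)
  h <- tibble(
    time = seq_len(n) * 0.05,
    phi = stats::runif(n, 0, 2 * pi),
    theta = stats::runif(n, 0.2, pi - 0.2),
    sigma_phi = 0.1,
    sigma_theta = 0.1,
    height = stats::runif(n, 0.2, 0.75),
    biasf = 15
  )
  attr(h, "cv_names") <- c("phi", "theta")
  attr(h, "periodic") <- list(phi = c(0, 2 * pi), theta = NULL)
  h
}
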