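## Plain-text input/output: one-column value files, two-column (group,value)
## files, summary writers and deterministic fixture generation.

#' Read two groups of non-negative observations
#'
#' Accepts either two one-column files (one value per line, header tolerated)
#' or a single two-column CSV `group,value`; in the latter case groups are
#' keyed by first-seen order. Blank lines are skipped.
#'
#' @param path_or_paths One path (two-column mode) or a character vector of
#'   two paths (one file per group).
#' @return A list of two numeric vectors, named by group label where
#'   available.
#' @export
read_groups <- function(path_or_paths) {
  for (p in path_or_paths) {
    if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  if (length(path_or_paths) == 2L) {
    out <- lapply(path_or_paths, .read_value_column)
    names(out) <- basename(path_or_paths)
  } else if (length(path_or_paths) == 1L) {
    df <- utils::read.csv(path_or_paths, header = .has_header(path_or_paths),
                          col.names = c("group", "value"),
                          blank.lines.skip = TRUE,
                          colClasses = c("character", "numeric"))
    groups <- unique(df$group)
    if (length(groups) < 2L) {
      stop("format error: two-column input must contain at least 2 groups",
           call. = FALSE)
    }
    if (length(groups) > 2L) {
      warning("more than 2 groups found; using the first two by appearance",
              call. = FALSE)
      groups <- groups[1:2]
    }
    out <- lapply(groups, function(g) df$value[df$group == g])
    names(out) <- groups
  } else {
    stop("supply one two-column file or exactly two one-column files",
         call. = FALSE)
  }
  for (i in seq_along(out)) {
    bad <- which(out[[i]] < 0)
    if (length(bad)) {
      stop(sprintf("parse error: negative value in group '%s' (entry %d)",
                   names(out)[i], bad[1]), call. = FALSE)
    }
  }
  out
}

## internal: does the first non-blank line look like a header?
.has_header <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",")[[1]]
  suppressWarnings(any(is.na(as.numeric(fields[length(fields)]))))
}

.read_value_column <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) && is.na(vals[1])) {  # header line
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop(sprintf("parse error in %s at line %d: '%s'", path, bad[1],
                 lines[bad[1]]), call. = FALSE)
  }
  vals
}

#' Write a group summary as key-value text
#'
#' @param s A [group_summary()].
#' @param path Output file; CSV `key,value` rows.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(s, path) {
  stopifnot(inherits(s, "dln_summary"))
  df <- data.frame(key = c("n", "n0", "n1", "mu_hat", "sigma2_hat",
                           "delta_hat", "omega_hat"),
                   value = c(s$n, s$n0, s$n1, s$mu_hat, s$sigma2_hat,
                             s$delta_hat, dln_variance(s)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write deterministic two-group fixtures
#'
#' Samples one dataset per group from the given truths and writes them as a
#' two-column `group,value` CSV. Byte-identical on re-run with the same seed.
#'
#' @param params1,params2 [dln_params()] truths.
#' @param n1,n2 Group sizes (at least 1).
#' @param seed Integer seed (required: fixtures are meant to be
#'   reproducible).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(params1, params2, n1, n2, seed, path) {
  stopifnot(n1 >= 1, n2 >= 1)
  local_seed(seed)
  x1 <- rdln(n1, params1)
  x2 <- rdln(n2, params2)
  df <- data.frame(group = rep(c("g1", "g2"), c(n1, n2)),
                   value = c(x1, x2))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
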