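# Tabular file formats. Everything is TSV with '#'-prefixed metadata lines;
# writes are deterministic (no timestamps) so identical runs produce
# byte-identical files.

format_num <- function(x) formatC(x, digits = 17, format = "g")

provenance_header <- function(kind, extra = character(0)) {
  c(sprintf("# structplast %s: %s", as.character(utils::packageVersion("structplast")), kind),
    extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  rows <- do.call(paste, c(lapply(df, function(col)
    if (is.numeric(col)) format_num(col) else as.character(col)),
    sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.table(text = lines[body], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  attr(df, "meta_lines") <- body
  df
}

meta_value <- function(meta, key) {
  hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
}

#' Read and write synapse-count distributions
#'
#' TSV with columns `S`, `p` and `#` metadata lines; round trips are lossless
#' to 12 significant digits.
#'
#' @param x a [synapse_distribution].
#' @param path file path.
#' @export
write_distribution_tsv <- function(x, path) {
  p <- unclass(x)
  write_tsv_with_header(
    data.frame(S = seq_along(p) - 1, p = as.numeric(p)), path,
    provenance_header("synapse_distribution",
                      sprintf("# method: %s", attr(x, "method"))))
}

#' @rdname write_distribution_tsv
#' @export
read_distribution_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  if (!all(c("S", "p") %in% names(df))) stop("expected columns S, p in ", path)
  if (any(df$p < 0)) stop("negative probabilities in ", path)
  p <- numeric(max(df$S) + 1)
  p[df$S + 1] <- df$p
  if (abs(sum(p) - 1) > 1e-9) {
    warning("probabilities in ", path, " sum to ", format(sum(p)), "; normalising")
    p <- p / sum(p)
  }
  m <- meta_value(attr(df, "meta"), "method")
  synapse_distribution(p, method = if (is.null(m)) "file" else m)
}

#' Read and write experimental histograms
#'
#' TSV with columns `S`, `freq`; `N_exp` is carried in a metadata line.
#'
#' @param x an [experiment_data()].
#' @param path file path.
#' @param strict reject non-normalised frequencies instead of normalising.
#' @export
write_experiment_tsv <- function(x, path) {
  write_tsv_with_header(
    data.frame(S = seq_along(x$p) - 1, freq = x$p), path,
    provenance_header("experiment_data", sprintf("# N_exp: %d", x$N_exp)))
}

#' @rdname write_experiment_tsv
#' @export
read_experiment_tsv <- function(path, strict = FALSE) {
  df <- read_tsv_with_header(path)
  if (!all(c("S", "freq") %in% names(df)))
    stop("expected columns S, freq in ", path)
  n_exp <- meta_value(attr(df, "meta"), "N_exp")
  if (is.null(n_exp)) stop("missing '# N_exp:' metadata line in ", path)
  experiment_data(df$S, df$freq, as.integer(n_exp), normalize = !strict)
}

#' Read and write hysteresis traces
#' @param x a `hysteresis_trace` (see [run_hysteresis()]).
#' @param path file path.
#' @export
write_hysteresis_tsv <- function(x, path) {
  write_tsv_with_header(
    as.data.frame(x), path,
    provenance_header("hysteresis_trace",
                      c(sprintf("# vary: %s", attr(x, "vary")),
                        sprintf("# cycles: %d", attr(x, "cycles")))))
}

#' @rdname write_hysteresis_tsv
#' @export
read_hysteresis_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  if (!all(c("level", "mean_up", "mean_down") %in% names(df)))
    stop("expected columns level, mean_up, mean_down in ", path)
  gap <- df$mean_down - df$mean_up
  dl <- diff(df$level)
  area <- sum((gap[-1] + gap[-length(gap)]) / 2 * dl)
  structure(df, vary = meta_value(attr(df, "meta"), "vary"),
            cycles = as.integer(meta_value(attr(df, "meta"), "cycles") %||% 1L),
            loop_area = area,
            class = c("hysteresis_trace", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write sampled curves
#' @param x an [empirical_curve()].
#' @param path file path.
#' @export
write_curve_tsv <- function(x, path) {
  write_tsv_with_header(
    data.frame(x = attr(x, "x"), y = attr(x, "y")), path,
    provenance_header("empirical_curve"))
}

#' @rdname write_curve_tsv
#' @export
read_curve_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  if (!all(c("x", "y") %in% names(df))) stop("expected columns x, y in ", path)
  empirical_curve(df$x, df$y)
}

#' Read and write spike trains
#'
#' Two-column text: time in seconds and source (`pre` or `post`). Unsorted
#' times within a source are an error reporting the offending line.
#'
#' @param pre,post [spike_train()]s.
#' @param path file path.
#' @export
write_spike_trains_tsv <- function(pre, post, path) {
  df <- data.frame(time_s = c(pre$times, post$times),
                   source = c(rep("pre", length(pre$times)),
                              rep("post", length(post$times))))
  df <- df[order(df$time_s), ]
  write_tsv_with_header(df, path, provenance_header("spike_trains"))
}

#' @rdname write_spike_trains_tsv
#' @export
read_spike_trains_tsv <- function(path) {
  df <- read_tsv_with_header(path)
  if (!all(c("time_s", "source") %in% names(df)))
    stop("expected columns time_s, source in ", path)
  if (!all(df$source %in% c("pre", "post")))
    stop("source must be 'pre' or 'post' in ", path)
  lines <- attr(df, "meta_lines")
  for (src in c("pre", "post")) {
    idx <- which(df$source == src)
    bad <- idx[which(diff(df$time_s[idx]) <= 0) + 1]
    if (length(bad))
      stop(sprintf("unsorted %s spike time at line %d of %s", src,
                   lines[bad[1] + 1], path))
  }
  list(pre = spike_train(df$time_s[df$source == "pre"], "pre"),
       post = spike_train(df$time_s[df$source == "post"], "post"))
}

#' Read a sectioned key-value configuration file
#'
#' Format: `[section]` headers, `key = value` (or `key: value`) entries,
#' `#` comments. Values are converted to numeric where possible; everything
#' else stays character. Returns a nested named list.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (!is.na(num)) num else val
  }
  out
}
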