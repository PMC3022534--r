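# Shared internal helpers: seeded evaluation and strict TSV i/o.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# Read a tab-delimited file with a mandatory header, skipping '#' comment
# lines, and return a list(header = character, rows = list of character
# vectors, lines = original line numbers). Row field-count errors are the
# caller's responsibility so messages can cite the offending column set.
read_tsv_lines <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no header row found in ", file, call. = FALSE)
  }
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  body_idx <- idx[-1L]
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  list(header = header, rows = rows, lines = body_idx)
}

#' Write a data.frame as TSV with optional comment headers
#'
#' All tabular outputs of the package go through this writer: plain
#' tab-delimited text, a mandatory header row, and optional leading
#' `#` comment lines (tool version, seed, parameters). Output carries
#' no timestamps, so identical inputs give byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param comments character vector of comment lines (written without
#'   the `# ` prefix supplied).
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

pkg_version_string <- function() {
  paste0("synexpr ", as.character(utils::packageVersion("synexpr")))
}

# Integer check that tolerates doubles holding whole numbers.
is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < 1e-8
}
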