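# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Deterministic sub-stream seed from a master seed and a stream name
#'
#' Derived seeds stay below 2^31 so they remain valid R integers. The string
#' hash is stable across platforms, so adding one stream never reshuffles
#' another.
#' @noRd
seed_for <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Evaluate code under a local RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Cumulative sum within runs of a sorted grouping vector
#' @noRd
grouped_cumsum <- function(x, g) {
  if (length(x) == 0L) return(numeric(0))
  cs <- cumsum(x)
  first <- !duplicated(g)
  base <- cs[first] - x[first]
  r <- rle(as.character(g))
  cs - rep(base, r$lengths)
}

#' Row count per run of a sorted grouping vector, repeated per row
#' @noRd
grouped_n <- function(g) {
  r <- rle(as.character(g))
  rep(r$lengths, r$lengths)
}

# -- TSV dialect -------------------------------------------------------------
# Tab-separated, UTF-8, header row, '.' decimal separator, no quoting;
# missing values are empty strings.

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L)
      abort("%s: missing required column(s): %s", path,
            paste(miss, collapse = ", "))
  }
  df
}

write_tsv_strict <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Check membership in a closed vocabulary
#' @noRd
check_vocab <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0L)
    abort("invalid %s value(s): %s (allowed: %s)", what,
          paste(bad, collapse = ", "), paste(vocab, collapse = ", "))
  invisible(x)
}

LIFESTYLES <- c("free_living", "extracellular", "cytoplasmic", "intranuclear")
ORGANELLE_STATUSES <- c("atp_mito_or_plastid", "no_atp_mito")
PATHWAY_GROUPS <- c("DDR", "replication", "metabolic", "housekeeping")
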