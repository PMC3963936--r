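# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a deterministic sub-seed for a pipeline stage, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("%s must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("%s must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Path to a packaged plain-text data asset.
stunmird_extdata <- function(file) {
  p <- system.file("extdata", file, package = "stunmird")
  if (!nzchar(p)) stop(sprintf("packaged data asset '%s' not found", file), call. = FALSE)
  p
}

# Read a packaged "# key=value ..." headed CSV, returning list(meta, data).
read_headed_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, gregexpr("[A-Za-z0-9_]+=[^ ]+", h))[[1]]
    for (pair in kv) {
      key <- sub("=.*", "", pair)
      meta[[key]] <- sub("^[^=]+=", "", pair)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stop(sprintf("no data rows in '%s'", path), call. = FALSE)
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  list(meta = meta, data = df)
}
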