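# Internal helpers shared across modules.

#' @importFrom stats rbinom sd phyper dhyper setNames
#' @importFrom utils packageVersion combn
NULL

# Stable 32-bit string hash (polynomial rolling hash).  Used to derive
# per-item RNG seeds from a base seed and an identifier so that results do
# not depend on the order in which items are processed.
pe_hash_string <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

pe_derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.integer(seed) + pe_hash_string(key)) %% 2147483647L)
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
pe_with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

pe_log <- function(..., verbose = getOption("pathextend.verbose", TRUE)) {
  if (isTRUE(verbose)) message("pathextend: ", ...)
}

# TSV writer with '#'-prefixed provenance header lines.
pe_write_tsv <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

pe_provenance_header <- function(subcommand, seed = NULL, config = NULL,
                                 timestamp = TRUE) {
  lines <- paste0("pathextend ", as.character(utils::packageVersion("pathextend")),
                  " ", subcommand)
  if (timestamp) lines <- c(lines, paste0("generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(seed)) lines <- c(lines, paste0("seed: ", seed))
  if (!is.null(config)) {
    lines <- c(lines, paste0("config: ", paste(names(config), unlist(config),
                                               sep = "=", collapse = " ")))
  }
  lines
}
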