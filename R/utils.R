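#' @keywords internal
"_PACKAGE"

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stage tag.
# Keeps all seeds in [1, 2^31 - 2]; exact in double arithmetic (< 2^53).
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (as.numeric(seed) * 69069 + h * 30011 + 1) %% 2147483629
  as.integer(val + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_srm <- function(..., class = "srmquant_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# FNV-1a hash of a character scalar, hex string; used to stamp outputs with
# a configuration fingerprint without a hashing dependency.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    # keep within exact-double range while mixing
    h <- (as.numeric(h + 2^30) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# CSV writer/reader with a '#'-prefixed provenance header block.
write_stage_csv <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", header), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
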