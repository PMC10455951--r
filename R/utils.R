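# Internal helpers shared across modules.

# The 20 proteinogenic amino acids, alphabetical one-letter codes.
IP_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#'
#' All stochastic generators in the package funnel randomness through this
#' helper so that they are pure functions of (parameters, seed) and never
#' perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
ip_with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable non-cryptographic content hash (FNV-1a, 32-bit) used to stamp
# pipeline outputs with the configuration they were produced from.
ip_fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte (b < 256); h itself can exceed .Machine
    # integer range, so avoid bitwXor on the full value
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply, split to stay within double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

ip_stop <- function(..., class = "immunopept_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

ip_is_sequence <- function(x) {
  grepl(paste0("^[", paste(IP_AA, collapse = ""), "]+$"), x)
}

# Random peptide over the 20-letter alphabet (uniform positions), vectorised.
ip_random_peptides <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(IP_AA, length, replace = TRUE), collapse = "")
  }, character(1))
}
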