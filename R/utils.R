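# Internal deterministic seed derivation.
#
# Per-gene (and per-fold, per-run) RNG streams are derived from the master
# seed plus string labels, so that results do not depend on gene order or on
# how work is split across workers. All arithmetic stays below 2^53 so the
# double computations are exact; results stay below 2^31 so they are valid
# R seeds.

.MOD <- 2147483629  # largest prime < 2^31

.hash_string <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% .MOD
  h
}

.derive_seed <- function(master, ...) {
  h <- master %% .MOD
  for (part in list(...)) {
    h <- (h * 69069 + 1) %% .MOD
    h <- (h + .hash_string(paste0(part))) %% .MOD
  }
  as.integer(h)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Lexicographic (byte-order) sort, independent of the user's locale.
.csort <- function(x) sort(x, method = "radix")
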