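# Internal helpers: classed conditions, seeded evaluation, strand handling.

usage_error <- function(msg) {
  stop(structure(class = c("seqfoot_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg) {
  stop(structure(class = c("seqfoot_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

parse_error <- function(msg, line = NA_integer_) {
  full <- if (is.na(line)) msg else sprintf("line %d: %s", line, msg)
  stop(structure(class = c("seqfoot_parse_error", "seqfoot_data_error",
                           "error", "condition"),
                 list(message = full, call = sys.call(-1), line = line)))
}

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Normalize user-facing strand spellings to "+"/"-".
norm_strand <- function(strand) {
  out <- rep(NA_character_, length(strand))
  out[strand %in% c("+", "forward", "fwd", "F", "sense")] <- "+"
  out[strand %in% c("-", "reverse", "rev", "R", "antisense")] <- "-"
  if (anyNA(out))
    data_error(sprintf("unrecognized strand value(s): %s",
                       paste(unique(strand[is.na(out)]), collapse = ", ")))
  out
}

# Normalize stratum names; long and short forms accepted.
norm_stratum <- function(stratum) {
  map <- c(forward = "forward", fwd = "forward", "+" = "forward",
           reverse = "reverse", rev = "reverse", "-" = "reverse",
           combined = "combined", comb = "combined", both = "combined")
  if (length(stratum) != 1L || !stratum %in% names(map))
    usage_error(sprintf("unknown stratum '%s' (use forward, reverse or combined)",
                        paste(stratum, collapse = ",")))
  unname(map[stratum])
}

stratum_suffix <- c(forward = "fwd", reverse = "rev", combined = "comb")

`%||%` <- function(a, b) if (is.null(a)) b else a
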