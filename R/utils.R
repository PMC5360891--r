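#' @keywords internal
"_PACKAGE"

# Symptom keys in diary order; the first four are the "major" symptoms.
SYMPTOM_KEYS <- c("chest_tightness", "breathlessness", "sputum_volume",
                  "sputum_purulence", "cold_sore_throat", "run_down")
MAJOR_KEYS <- SYMPTOM_KEYS[1:4]
SYMPTOM_LEVELS <- c("improved", "no_change", "worse")

FSM_STATES <- c("NORMAL", "TRANSITIONAL", "EXACERBATION")

#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the R RNG, evaluates `expr`, then restores the previous RNG state so
#' that seeded generators do not disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a root seed; kept below 2^31.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # FNV-1a 32-bit over the key characters, folded into [0, 2^31)
  h <- 2166136261
  for (ch in utf8ToInt(key)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, ch)  # ch < 256: xor touches the low byte only
    # multiply mod 2^32 in 16-bit halves to stay within double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_sessions_frame <- function(sessions) {
  needed <- c("patient_id", "t", SYMPTOM_KEYS, "reliever_increased",
              "antibiotics", "steroids", "hcp_contact")
  missing <- setdiff(needed, names(sessions))
  if (length(missing) > 0L)
    stopf("sessions are missing column(s): %s", paste(missing, collapse = ", "))
  for (k in SYMPTOM_KEYS) {
    bad <- !sessions[[k]] %in% SYMPTOM_LEVELS
    if (any(bad))
      stopf("column '%s' has values outside {%s} at row(s) %s", k,
            paste(SYMPTOM_LEVELS, collapse = ", "),
            paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(sessions$t < 0)) stopf("session times must be non-negative")
  invisible(sessions)
}

check_sorted_single_patient <- function(sessions) {
  if (nrow(sessions) == 0L) return(invisible(sessions))
  if (length(unique(sessions$patient_id)) > 1L)
    stopf("expected sessions from a single patient, got %d patients",
          length(unique(sessions$patient_id)))
  if (is.unsorted(sessions$t, strictly = TRUE))
    stopf("sessions must be strictly increasing in time for patient '%s'",
          sessions$patient_id[1])
  invisible(sessions)
}

split_patients <- function(sessions) {
  split(sessions, factor(sessions$patient_id, levels = unique(sessions$patient_id)))
}
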