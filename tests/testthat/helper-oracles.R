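# Independent brute-force oracles used to validate the scanning algorithms.

# does the window [i, j] of a status vector qualify as a run?
# ends must be strict hom; het/missing counts within budget ("soft" markers
# are free); if any budgeted interruption is present, the stretches before
# the first and after the last interruption must each carry >= min_flank
# strict hom markers
window_qualifies <- function(status, i, j, max_het, max_miss,
                             min_flank = 5) {
  if (status[i] != "hom" || status[j] != "hom") return(FALSE)
  w <- status[i:j]
  if (sum(w == "het") > max_het) return(FALSE)
  if (sum(w == "miss") > max_miss) return(FALSE)
  inter <- which(w == "het" | w == "miss")
  if (length(inter)) {
    lead <- sum(w[seq_len(inter[1] - 1L)] == "hom")
    trail <- sum(w[seq(inter[length(inter)] + 1L, length(w))] == "hom")
    if (lead < min_flank || trail < min_flank) return(FALSE)
  }
  TRUE
}

# exhaustive O(n^2) enumeration with longest-first selection and
# re-derivation: the longest qualifying window in a stretch is taken (ties
# to the leftmost start) and the stretch on each side is searched again;
# written independently of the package's scanner
brute_force_runs <- function(status, min_markers, max_het, max_miss,
                             min_flank = 5) {
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < min_markers) return(NULL)
    best <- NULL
    for (s in lo:hi) {
      for (j in s:hi) {
        if (j - s + 1L >= min_markers &&
            window_qualifies(status, s, j, max_het, max_miss, min_flank) &&
            (is.null(best) || j - s > best[2] - best[1]))
          best <- c(s, j)
      }
    }
    if (is.null(best)) return(NULL)
    rbind(recurse(lo, best[1] - 1L), best, recurse(best[2] + 1L, hi))
  }
  m <- recurse(1L, length(status))
  if (is.null(m)) {
    return(data.frame(start_idx = integer(), end_idx = integer()))
  }
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start_idx = as.integer(m[, 1]), end_idx = as.integer(m[, 2]))
}

# direct statement of the shared-homozygosity rule, marker by marker
brute_shared_status <- function(calls) {
  n_aff <- nrow(calls)
  apply(calls, 2, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) return("miss")
    agree <- max(sum(obs == "AA"), sum(obs == "BB"))
    deviants <- length(obs) - agree
    if (deviants == 0) return("hom")
    if (n_aff >= 3 && deviants == 1 && agree >= 2) return("soft")
    "het"
  })
}

# random call string with given status mix
random_calls <- function(n, p_het = 0.3, p_miss = 0.1) {
  u <- runif(n)
  out <- ifelse(u < p_miss, NA_character_,
                ifelse(u < p_miss + p_het, "AB",
                       sample(c("AA", "BB"), n, replace = TRUE)))
  out
}
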