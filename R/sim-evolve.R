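## Neutral substitution process with CpG hypermutability.

## CpG membership of every site (TRUE if site is the C or the G of a CG)
cpg_sites <- function(ch) {
  n <- length(ch)
  out <- logical(n)
  if (n < 2L) return(out)
  cg <- which(ch[-n] == "C" & ch[-1L] == "G")
  out[cg] <- TRUE
  out[cg + 1L] <- TRUE
  out
}

#' Evolve a sequence under a two-parameter substitution process
#'
#' Simulates a continuous-time Markov jump process for `age` million
#' years at total rate `rate_M` substitutions per site per Myr, with
#' transition:transversion rate ratio `kappa` and the per-site rate
#' multiplied by `cpg_multiplier` while the site sits in a CpG
#' dinucleotide (context re-evaluated after every substitution, so the
#' process creates and destroys CpG sites as real deamination does).
#' Substitutions only; length is unchanged.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param age elapsed time in Myr (>= 0).
#' @param config a [sim_config] (only `rate_M`, `cpg_multiplier`,
#'   `kappa` are used), or a list with those elements.
#' @param detail if `TRUE`, also return the event log.
#' @return the evolved sequence, or (with `detail = TRUE`) a list with
#'   `sequence`, `n_events` and `events` (data frame: site, from, to,
#'   transition flag).
#' @export
evolve_sequence <- function(sequence, age, config = sim_config(),
                            detail = FALSE) {
  stopifnot(age >= 0)
  M <- config$rate_M; mult <- config$cpg_multiplier; kappa <- config$kappa
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (age == 0 || n == 0L) {
    if (detail) return(list(sequence = sequence, n_events = 0L,
                            events = data.frame()))
    return(sequence)
  }
  in_cpg <- cpg_sites(ch)
  rates <- M * ifelse(in_cpg, mult, 1)
  total <- sum(rates)
  p_ts <- kappa / (kappa + 2)
  t <- 0
  ev_site <- integer(0); ev_from <- character(0); ev_to <- character(0)
  repeat {
    t <- t + rexp(1, total)
    if (t > age) break
    i <- sample.int(n, 1L, prob = rates)
    from <- ch[i]
    to <- if (runif(1) < p_ts) TRANSITION[[from]] else
      sample(setdiff(DNA_BASES, c(from, TRANSITION[[from]])), 1L)
    ch[i] <- to
    if (detail) {
      ev_site <- c(ev_site, i); ev_from <- c(ev_from, from)
      ev_to <- c(ev_to, to)
    }
    ## re-evaluate CpG context around the mutated site
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    idx <- lo:hi
    new_cpg <- cpg_sites(ch[max(1L, lo - 1L):min(n, hi + 1L)])
    new_cpg <- new_cpg[idx - max(1L, lo - 1L) + 1L]
    rates[idx] <- M * ifelse(new_cpg, mult, 1)
    total <- sum(rates)
  }
  out <- chars_seq(ch)
  if (detail) {
    ev <- data.frame(site = ev_site, from = ev_from, to = ev_to)
    if (nrow(ev)) ev$transition <- TRANSITION[ev$from] == ev$to
    list(sequence = out, n_events = length(ev_site), events = ev)
  } else out
}
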