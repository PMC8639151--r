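# Lightweight fixture builders and independent oracles used across tests.

# fast footfall-sequence data.frame from a limb vector
ff_seq <- function(limbs, step_type = rep("plantar", length(limbs))) {
  structure(list(time_s = seq_along(limbs) * 0.05,
                 limb = limbs, step_type = step_type),
            class = "data.frame", row.names = seq_along(limbs))
}

# reference-cycle table from contact-onset times
ref_cycles <- function(contacts) {
  n <- length(contacts) - 1
  data.frame(contact_s = contacts[seq_len(n)],
             next_contact_s = contacts[seq_len(n) + 1],
             stride_s = diff(contacts))
}

# footfall event table for one limb from contact/liftoff times
limb_events <- function(limb, contact, liftoff,
                        step_type = rep("plantar", length(contact)),
                        speed = 50) {
  data.frame(limb = limb, contact_s = contact, liftoff_s = liftoff,
             toe_x_cm = speed * contact, step_type = step_type)
}

# --- independent oracles -----------------------------------------------------

# greedy non-overlapping RI, implemented recursively on a collapsed string
# (independent route from the package's while-loop scan)
ri_oracle <- function(limbs, step_type = rep("plantar", length(limbs))) {
  pats <- vapply(normal_step_patterns(), paste, character(1), collapse = "")
  s <- limbs[step_type != "dorsal"]
  n <- length(s)
  if (n < 4) return(NA_real_)
  count <- function(v) {
    if (length(v) < 4) return(0L)
    if (paste(v[1:4], collapse = "") %in% pats) 1L + count(v[-(1:4)])
    else count(v[-1])
  }
  100 * (count(s) * 4) / n
}

# rolling-window CPI against the explicit 20-string rotation closure of the
# six normal patterns (literal matching against the expanded set)
cpi_oracle <- function(limbs) {
  rots <- unique(unlist(lapply(normal_step_patterns(), function(p) {
    vapply(0:3, function(k) paste(c(p, p)[(k + 1):(k + 4)], collapse = ""),
           character(1))
  })))
  n <- length(limbs)
  if (n < 4) return(0)
  wins <- n - 3L
  ok <- vapply(seq_len(wins), function(i)
    paste(limbs[i:(i + 3L)], collapse = "") %in% rots, logical(1))
  100 * sum(ok) / wins
}

# brute-force Watson U2: O(N^2) EDF evaluation at the pooled points
watson_u2_bruteforce <- function(a, b) {
  v <- sort(c(a, b))
  Fd <- vapply(v, function(t) mean(a <= t), numeric(1))
  Gd <- vapply(v, function(t) mean(b <= t), numeric(1))
  d <- Fd - Gd
  (length(a) * length(b) / length(v)^2) * sum((d - mean(d))^2)
}

# small synthetic cohort used by several suites (events only, fast)
make_test_cohort <- function(seed = 42, n_animals = 4, passes = 6,
                             conditions = default_conditions()) {
  cfg <- synthetic_config(conditions = conditions, n_animals = n_animals,
                          passes_per_animal = passes,
                          strides_per_pass = c(5, 9), seed = seed)
  generate_cohort(cfg)
}
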