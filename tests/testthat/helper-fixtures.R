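# Shared fixtures and independent oracles used across the suite.

# minimal valid quadrat observation table
toy_obs <- function() {
  data.frame(
    summit_id = rep(c("GUL1", "GUL1", "GUL2"), each = 2),
    aspect = rep(c("N", "S", "N"), each = 2),
    quadrat_index = rep(c(1, 1, 2), each = 2),
    year = 2014,
    species_id = c("spA", "spB", "spA", "spC", "spB", "spC"),
    cover = c(30, 20, 10, 5, 8, 2),
    stringsAsFactors = FALSE)
}

toy_summits <- function() {
  data.frame(summit_id = c("GUL1", "GUL2"), elevation = c(3530, 3600),
             stringsAsFactors = FALSE)
}

# independent pairwise oracle: plain set arithmetic on species index sets
oracle_pair <- function(v1, v2) {
  s1 <- which(v1 > 0); s2 <- which(v2 > 0)
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  cc <- length(setdiff(s2, s1))
  m <- min(b, cc)
  bsor <- (b + cc) / (2 * a + b + cc)
  bsim <- if (a + m == 0) 0 else m / (a + m)
  c(a = a, b = b, c = cc, bsor = bsor, bsim = bsim, bsne = bsor - bsim)
}

# independent multiple-site oracle: explicit pair enumeration with set
# operations (no matrix algebra)
oracle_multisite <- function(inc) {
  sets <- apply(inc, 1, function(r) which(r > 0), simplify = FALSE)
  Si <- lengths(sets)
  ST <- length(unique(unlist(sets)))
  n <- length(sets)
  sum_min <- 0; sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bij <- length(setdiff(sets[[i]], sets[[j]]))
      bji <- length(setdiff(sets[[j]], sets[[i]]))
      sum_min <- sum_min + min(bij, bji)
      sum_max <- sum_max + max(bij, bji)
    }
  }
  asum <- sum(Si) - ST
  bsim <- if (asum + sum_min == 0) 0 else sum_min / (asum + sum_min)
  denom <- 2 * asum + sum_min + sum_max
  bsor <- if (denom == 0) 0 else (sum_min + sum_max) / denom
  c(bsor = bsor, bsim = bsim, bsne = bsor - bsim)
}

# random incidence matrix with no empty sites
rand_incidence <- function(n_sites, n_species, p = 0.5) {
  repeat {
    m <- matrix(stats::rbinom(n_sites * n_species, 1, p),
                n_sites, n_species)
    if (all(rowSums(m) > 0)) return(m)
  }
}

# hourly series fixture: one logger, one day (or more), given temperatures
hourly_series <- function(temps, start = "2018-06-01 00:00:00",
                          logger = "L1") {
  data.frame(logger_id = logger, window = 1L,
             timestamp = seq(as.POSIXct(start, tz = "UTC"), by = "hour",
                             length.out = length(temps)),
             temperature = temps, stringsAsFactors = FALSE)
}
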