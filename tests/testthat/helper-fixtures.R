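# Shared fixtures, computed lazily once per test run. The default synthetic
# time course (ages 0/1/3/5/7, quadruplicate) is the study condition for
# the end-to-end trend checks; smaller bespoke fixtures are built inside
# the tests that need them.

.fixtures <- new.env(parent = emptyenv())

shared_targets <- function() {
  if (is.null(.fixtures$targets))
    .fixtures$targets <- build_target_list(target_list_config())
  .fixtures$targets
}

shared_timecourse <- function() {
  if (is.null(.fixtures$tc))
    .fixtures$tc <- generate_timecourse(seed = 1L)
  .fixtures$tc
}

shared_annotated_tc <- function() {
  if (is.null(.fixtures$atc))
    .fixtures$atc <- annotate_timecourse(shared_timecourse(),
                                         shared_targets())
  .fixtures$atc
}

# one day-7 sample (replicate 1) and its ground truth
shared_day7 <- function() {
  tc <- shared_timecourse()
  for (s in tc$samples)
    if (s$age_days == 7 && s$replicate == 1L) return(s)
  stop("day-7 sample missing from fixture")
}

shared_day0 <- function() {
  tc <- shared_timecourse()
  for (s in tc$samples)
    if (s$age_days == 0 && s$replicate == 1L) return(s)
  stop("day-0 sample missing from fixture")
}

# random valid composition for property loops
random_composition <- function() {
  elemental_composition(C = sample(0:60, 1), H = sample(0:120, 1),
                        O = sample(0:8, 1), Na = sample(0:2, 1),
                        K = sample(0:1, 1), C13 = sample(0:2, 1))
}

# weighted median helper for cluster-location checks
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1]]
}
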