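# shared fixture builders; everything is generated in code at test time

random_profile <- function(n, mean = 5) {
  profile_from_counts(rpois(n, mean))
}

# per-base profile (one run per base) so run-level == base-level
base_profile <- function(values, chrom = "chr1") {
  coverage_profile(chrom, seq_along(values) - 1L, seq_along(values),
                   as.integer(values))
}

gauss_identity <- function() noise_spec("gaussian", transform = "identity")

all_noises <- function(phi = 4) {
  list(poisson = noise_spec("poisson"),
       gaussian = noise_spec("gaussian"),
       nbinom = noise_spec("nbinom", phi = phi))
}

# worked five-segment profile: theta (1,3,10,9,2), boundaries every 10 bases
worked_rule_segmentation <- function() {
  p <- profile_from_counts(rep(c(1, 3, 10, 9, 2), each = 10))
  solve_penalized(p, "unconstrained", noise_spec("poisson"), 0.1)
}

worked_labels <- function() {
  label_set("chr1", c(0L, 20L, 40L), c(10L, 30L, 50L),
            c("noPeaks", "peakStart", "peakEnd"))
}
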