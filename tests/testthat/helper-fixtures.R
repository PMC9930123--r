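# Shared fixtures, all built in code.

# Hydrogen-bonded water dimer (acceptor atoms 1-3, donor 4-6), matching the
# packaged inst/extdata/water_dimer.xyz geometry.
water_dimer_system <- function() {
  a <- 104.52 * pi / 180
  r <- 0.9572
  acc <- rbind(c(0, 0, 0),
               r * c(-cos(a / 2), 0, sin(a / 2)),
               r * c(-cos(a / 2), 0, -sin(a / 2)))
  don_o <- c(2.97, 0, 0)
  h1 <- don_o + r * c(-1, 0, 0)
  h2 <- don_o + r * c(cos(pi - a), sin(pi - a), 0)
  mol_system(rep(c("O", "H", "H"), 2), rbind(acc, don_o, h1, h2))
}

water_dimer_snapshot <- function() {
  sys <- water_dimer_system()
  list(qm_system = sys,
       partition = fragment_partition(1:3, 4:6, 0L, 0L, 6),
       mm_region = mm_region(),
       provenance = "water dimer fixture")
}

he_pair_snapshot <- function(distance) {
  sys <- mol_system(c("He", "He"), rbind(c(0, 0, 0), c(distance, 0, 0)))
  list(qm_system = sys,
       partition = fragment_partition(1L, 2L, 0L, 0L, 2),
       mm_region = mm_region(),
       provenance = sprintf("He pair at %.1f A", distance))
}

ion_pair_snapshot <- function(distance = 20) {
  sys <- mol_system(c("Li", "F"), rbind(c(0, 0, 0), c(distance, 0, 0)),
                    charge = 0L)
  list(qm_system = sys,
       partition = fragment_partition(1L, 2L, 1L, -1L, 2),
       mm_region = mm_region(),
       provenance = sprintf("Li+ F- at %.1f A", distance))
}

ammonium_snapshot <- function(n_total = 8, n_qm = 2, seed = 11,
                              polarizable = FALSE) {
  raw <- generate_synthetic_snapshot("ammonium", n_total, seed = seed,
                                     polarizable = polarizable)
  partition_closest_n(raw, n_qm)
}

# Brute-force classical potential sum (independent of the package path).
brute_potential <- function(pos, q, points) {
  apply(points, 1, function(p) {
    sum(q / sqrt(rowSums((pos - matrix(p, nrow(pos), 3, byrow = TRUE))^2)))
  })
}
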