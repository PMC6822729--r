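# Generates the synthetic fixture communities shipped in inst/extdata/.
# Three communities emulating the size, density and out-degree structure of
# the assayed prairie-soil communities:
#   A: 18 isolates, density 0.258, bimodal out-degrees (super-killers)
#   B: 17 isolates, density 0.327, even out-degrees
#   C: 17 isolates, density 0.294, unimodal moderate out-degrees
# Run from the package root; regenerating with the same seed is bit-identical.
library(antagonet)

set.seed(20260901)
profiles <- list(
  A = community_profile(18, "bimodal", target_density = 0.258),
  B = community_profile(17, "even", target_density = 0.327,
                        range = c(0, 12)),
  C = community_profile(17, "unimodal", target_density = 0.294,
                        mean = 5, sd = 2.5))
for (id in names(profiles)) {
  net <- simulate_community(profiles[[id]],
                            labels = sprintf("%s%02d", tolower(id), 1:profiles[[id]]$n_isolates))
  write_inhibition_matrix(
    net, file.path("inst", "extdata",
                   sprintf("synthetic-community-%s.csv", id)))
}
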