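# netrestore

Collapse and restoration dynamics for mutualistic plant-pollinator
networks.

Mutualistic communities are bipartite: plants and pollinators interact
across guilds, and a species that loses all of its partners goes
extinct, so a single loss can cascade. `netrestore` is for ecologists
and network scientists who want to ask the recovery question
quantitatively: after a partial collapse, **in what order should
extirpated species be reintroduced?** The package simulates species-loss
perturbations and obligate-mutualism extinction cascades, then compares
network-topology-guided reintroduction strategies (degree, harmonic
closeness, betweenness, and a greedy rule maximizing the projection's
effective nearest-neighbour degree β_eff) against a random null, under
three levels of dynamical description and three recovery criteria.

## The models and criteria

Species abundances follow a mutualistic community model with logistic
growth, intraguild competition, a Holling type II mutualistic gain, and
immigration. For plant *i* (pollinators symmetric):

    dP_i/dt = P_i ( α − Σ_j β_ij P_j + Σ_k γ_ik A_k / (1 + h Σ_k γ_ik A_k) ) + μ,
    γ_ij = ε_ij γ0 / D_i^p

The full n-D system reduces to a 2-D model (one effective abundance per
guild, driven by degree-weighted average strengths ⟨γ_P⟩, ⟨γ_A⟩) and to
a 1-D model on the one-mode projection,

    dx/dt = B + x (1 − x/K)(x/C − 1) + β_eff x² / (D + (E+H) x),

whose single topological control parameter β_eff = ⟨s²⟩/⟨s⟩ grows as the
network is rebuilt. After every reintroduction three criteria are
recorded: mean abundance of survivors (X), settling time (ST; first step
after which all abundances change < 10⁻⁶ for 5 consecutive steps), and
persistence (P; surviving species over the intact species count).
Network structure is summarized by size S, asymmetry A, connectance C,
and NODF nestedness (0 = non-nested, 100 = perfectly nested).

## Worked example

Generate a nested synthetic network, knock out 60% of its species under
generalist-preferred sampling, and compare degree-guided restoration
with the random null under the 1-D model:

```r
library(netrestore)

net <- generate_network(generator_config(10, 20, 0.2,
                                         attachment_bias = 1, seed = 1))
network_attributes(net)
#> S = 30 (n = 10 plants, m = 20 pollinators), A = 2.000, C = 0.200, NODF = 20.20, L = 40

out <- perturb(net, perturbation_scenario("generalist_preferred", 0.6,
                                          "both", seed = 3))
out
#> <perturbation_outcome: 18 primary + 12 secondary extinctions, 0 species survive>

removed <- c(out$primary_removed, out$secondary_removed)
for (kind in c("degree", "random")) {
  sq <- rank_sequence(net, removed,
                      restoration_strategy(kind, seed = 7))
  run <- simulate_restoration(net, out, sq, model = "1D")
  cat(kind, ": mean X =", round(mean(run$per_step$X), 2),
      " mean ST =", round(mean(run$per_step$ST), 2), "\n")
}
#> degree : mean X = 5.51  mean ST = 6.23
#> random : mean X = 0.42  mean ST = 8.6
```

Reintroducing hubs first (degree) raises the effective
nearest-neighbour degree fastest, tips the 1-D system to its
high-abundance branch within a few steps, and yields a 13-fold higher
mean abundance over the restoration pathway than random ordering; both
pathways end at the same fully restored equilibrium.

The full factorial experiment (networks × models × 3 scenarios × 3
removal fractions × strategies × 10 ensembles) runs through
`run_experiment()`, with `summarize_experiment()`,
`identify_winner()`, and `attribute_correlations()` reproducing the
winner tables and the attribute-criterion statistics;
`cmd_generate()` / `cmd_run()` / `cmd_enumerate()` drive the same
pipeline from a YAML config (a thin CLI wrapper lives in
`inst/scripts/netrestore-cli.R`).

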