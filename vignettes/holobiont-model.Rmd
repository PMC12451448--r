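---
title: "The holosim model: assumptions, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The holosim model: assumptions, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosim)
```

## The model in brief

`holosim` simulates a holobiont system as two nested Wright–Fisher-style
processes. Hosts form a constant-sized haploid population reproducing
clonally with non-overlapping generations; microbes form large communities
of fixed total size inside each host and in a shared environmental pool,
also replaced wholesale each microbial generation. Every community change is
a multinomial sampling event whose per-taxon probability is the product of
fitness and relative abundance in the source community, so drift, selection
and immigration act simultaneously and community totals are conserved
exactly.

Fitness everywhere is Gaussian stabilizing selection towards an
environmental optimum, `exp(-(phi - E)^2 / s)`. Three optima are in play:
the external condition `E_tM` for microbes in the environmental pool; the
composite within-host condition `E_tMh = I*phi_hg + (1 - I)*E_tM` for
microbes inside a host (a skin-versus-gut-microbiome dial: `I = 0` is full
external exposure, `I = 1` a fully host-determined milieu); and the host
generation's condition for hosts themselves, applied to the phenotype
`phi_h = G*phi_hg + (1 - G)*phi_hM`. With the default `G = 0` and a single
fixed genetic trait value, hosts have no adaptive potential of their own:
all host adaptation is mediated by the microbiome, which is the regime the
simulator is designed to probe. `phi_hM` is the abundance-weighted mean
microbiome trait — each microbial individual contributes equally, the
natural choice in an individual-based model (a presence-weighted mean over
taxa is the main alternative; it would overweight rare taxa).

## One host generation, step by step

The generation cycle orders events as follows. The offspring-assembly draw
that created the current communities counts as microbial step 1 of the
generation; steps `2..T_M` are within-host updates. Concretely, for each of
the `T_M` microbial steps the environmental pool is renewed first (so host
shedding reflects the previous step's communities), and from step 2 onwards
every host community is resampled at retention `P` from itself and `1 - P`
from the just-renewed pool. This accounting is forced by a limiting case:
with complete vertical inheritance (`X = 1`) and `T_M = 1` a host lineage
must have *no* opportunity to recruit new microbes — if a retention update
also ran in that configuration, 2% of the community would be environmental
every generation and closed transmission would be impossible to represent.

After the last microbial step, host fitness is evaluated, metrics are
recorded (prior to reproduction), parents are drawn with probability
proportional to fitness, and offspring communities are assembled from the
parent (`X`) and the environment as it stands after the final renewal
(`1 - X`). Host selection uses the final microbial-resolution environmental
value of the generation — the condition the hosts most recently experienced;
when `T_M = 1` this is exactly the host-resolution value. The alternative
(the generation's first value) is available via
`holosim_config(host_fitness_env = "start")` for sensitivity analysis; at
large `T_M` the two differ by at most one interpolation step.

When a sampling event draws *into* a host, both sources — including the
environmental pool — are weighted by within-host fitness at `E_tMh`
(destination-context weighting): the host environment filters colonizers.
The alternative, weighting each source by fitness in its own context, is
exposed as `fitness_context = "source"`. Destination weighting is the
default because host filtering of environmental microbes over repeated
microbial generations is the mechanism by which within-host selection shapes
the community.

## Environmental scenarios

Six scenarios combine three trends with two noise structures. Scenario 1
fluctuates about a constant mean; scenario 2 ramps the mean linearly from 0
(at the end of burn-in) to `mu_max` (default 2) at the final generation;
scenario 3 keeps mean 0 and ramps the SD from `sigma0` (default 0.5) to
`sigma_max` (default 1.5). Type A series are AR(1) with lag-1
autocorrelation `rho` (default 0.9) and innovation variance scaled by
`1 - rho^2` so the *marginal* SD matches the type-B counterpart; type B
draws each generation independently. A and B therefore differ only in
predictability, which is the comparison of interest. Values are clipped to
the trait range `[-2.5, 2.5]` by default, since trait values cannot exceed
that range and an optimum outside it is unreachable by any community. During
burn-in every scenario behaves as scenario 1, because burn-in exists to let
communities stabilize after the fitness-free founding draw; the burn-in
generations are counted within `T_H` and retained (flagged `is_burn_in`) in
the output so stabilization can be inspected rather than silently
discarded.

The microbial-resolution series is the host-resolution series linearly
interpolated `T_M` times within each generation; the final generation, which
has no successor, is held constant for its `T_M` steps (holding avoids
extrapolating a trend beyond the simulated horizon and affects only the last
generation). The default burn-in of 200 generations for 100 hosts is the
expected whole-population coalescence time of a neutral Wright–Fisher
population, about `2*N_e`; `simulate_coalescence()` reproduces this number
directly from the package's own parent-selection kernel.

```{r coalescence}
set.seed(1)
mean(simulate_coalescence(N_H = 100, replicates = 200))
```

## Numerical choices

*Integer allocation.* Proportions such as `P`/`1-P` or `Z`/`Y`/`1-Z-Y` are
converted to per-source draw counts by largest-remainder rounding, so the
split is deterministic and exact: with `P = 0.98` and `n_MH = 1e4`, exactly
200 individuals per update come from the environment. Remainder ties go to
the earlier source, with the host/parent source listed first. A stochastic
binomial split is available (`allocation = "binomial"`) for checking that
this determinism is not doing hidden work.

*Underflow.* At small `s` and extreme mismatch, `exp(-(phi - E)^2/s)` can
underflow to 0 for every taxon in a source. Sampling then falls back to
relative abundance alone, with a warning: the process stays defined in
arbitrarily harsh environments without biasing among taxa. The same
fallback guards parent selection when all host fitnesses underflow.

*Diversity scaling.* Alpha diversity is Shannon entropy scaled by its
maximum over the *global* taxon pool, `ln(N_M)`, not over realized
richness. Scaling by realized richness would make a host that lost half its
taxa but kept the survivors even look maximally diverse; the global scaling
makes taxon loss visible, which is precisely the signal of interest under
closed transmission.

*Seeds.* A single master seed drives everything. Per-run seeds are derived
by stable string hashing of (master seed, role, scenario, replicate, X,
T_M), so any run of a grid can be reproduced in isolation and execution
order is irrelevant. Environmental series are keyed by (scenario, replicate)
only; every `X`/`T_M` combination of a replicate sees the identical series,
which pairs the comparisons across transmission settings.

## Effective vertical inheritance

Vertical transmission at birth (`X`) is eroded by within-host turnover: each
of the `T_M - 1` retention updates keeps proportion `P` of the community in
expectation, so the expected fraction of parentally derived microbes at
reproduction is `X * P^(T_M - 1)`. With `P = 0.98` and 101 microbial
generations, even `X = 1` leaves about 13% parental ancestry.
`realized_vertical_inheritance()` verifies this by explicit tagging,
propagating parent-origin labels through the same sampling kernels by
treating tagged and untagged copies of each taxon as separate categories:

```{r evi}
expected_effective_vertical_inheritance(X = 1, P = 0.98, T_M = 101)
set.seed(2)
mean(realized_vertical_inheritance(X = 1, P = 0.98, T_M = 101,
                                   n_hosts = 10, n_MH = 2000, N_M = 20))
```

Under selection the realized fraction can deviate from the closed form
(adapted parental lineages are retained preferentially), which is why the
closed form is asserted only under neutrality.

## What the generator emulates — and what it does not

The synthetic environments and communities emulate the study conditions of
the modelling framework: hundreds of taxa with static uniform trait values,
fixed community sizes, clonal reproduction, selection of identical strength
in host and environment, and environmental change that is smooth (type A)
or white (type B) around simple trends. Real microbiomes violate most of
this: taxa evolve, community sizes fluctuate, host genetics vary and
interact with the microbiome, selection strengths differ between body sites
and environments, and environmental spectra are richer than AR(1). Passing
tests therefore demonstrate the internal consistency of the model and the
reproducibility of its qualitative regimes — the host–microbe fitness
antagonism under low `T_M`, its dissolution at high `T_M`, diversity
collapse under closed transmission — not predictions for any particular
natural system.

## Problem sizes

The package defaults mirror the full study conditions (`n_MH = 1e6`,
`n_ME = 1e8`, `T_H = 1500`, up to 15,120 runs in the full default sweep); these
are practical on a workstation for single runs but not for a full grid in
interactive use. The test and acceptance suites therefore run a reduced
configuration — 50 hosts, 50 taxa, `1e4` microbes per host, `1e5` in the
pool, 400 generations with a 100-generation burn-in, 5 replicates — chosen
to keep every qualitative contrast (antagonism in `X`, buffering by `T_M`,
diversity collapse at `X = 1`) well outside sampling noise while a complete
suite runs in minutes. Statistical checks on stochastic kernels use
10^3–10^4 draws on 3-taxon toy communities, where goodness-of-fit against
exact multinomial references is sharp.

## Known limitations

No microbial mutation or within-taxon variation; no host genetic variation
or evolution (the genetic trait is fixed and its weighting defaults to 0);
selection strength `s` is shared between host and environment contexts;
generations are non-overlapping and population sizes fixed, inherited from
the Wright–Fisher framing; and beta diversity is not tracked. These are
deliberate scope boundaries, not oversights; the module structure (fitness
kernels, community kernels, engine) is meant to make such extensions
localized.
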