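# t6duel

Agent-based simulation of type VI secretion system (T6SS) duels between
rod-shaped bacteria, with the evolutionary analysis needed to ask which
firing strategies can invade and persist.

## The problem

The T6SS is a contact-dependent weapon: a poisoned needle fired into
whichever cell happens to be adjacent. Species use it very differently —
some fire constantly at random (*Vibrio cholerae*-style), while
*Pseudomonas aeruginosa* famously holds fire and counterattacks from the
exact spot where it was stabbed (tit-for-tat). Whether and when such
retaliation can *evolve* is a question about spatial, contact-structured
competition, and answering it needs an explicit mechanical model of dense
cell groups plus game-theoretic bookkeeping on top.

`t6duel` is for researchers in microbial ecology and evolution who want a
tested, deterministic-under-seed implementation of that model: rigid
spherocylindrical cells growing in a 2-D resource patch, overlap relaxation
by regularized impulses, Poisson random firing, aimed multi-shot
retaliation, step-like intoxication (`N_hits` translocations, then lysis
after `1/k_lysis`), and growth costs for carrying and using the weapon.

## The model in brief

* Growth: `dV/dt = k_grow V` per cell (exact per-step exponential),
  division at `2V₀ + η` with noise, shared resource `dE/dt = −k_max ΣVᵢ`;
  depletion ends the run.
* Costs: `k_grow = k_max (1 − c_upfront − c·N_firings/dt)`, with a
  "cost-saving knockout" variant that pays like a random firer regardless
  of realized firings.
* Mechanics: contacts between capsules resolved by the regularized
  least-squares impulse system `(AᵀA + αM) p = −Aᵀd`, iterated to a
  residual-overlap tolerance.
* Combat: needles of length `L_needle`; a cell is hit when the needle
  passes within `R − L_penetration` of its axis; needles stop at the first
  cell entered; clonemates (and optionally designated genotype pairs) are
  immune; retaliators answer each non-clonemate hit next step with `n`
  reversed needles from the entry point.
* Evolution: invasion fitness `ω = ln(ΣV_end / ΣV_start)` per strategist;
  local and global (metapopulation) invasion indices, mutual-immunity
  (`p_s`), cheater and relatedness (`I`) weightings; pairwise invasibility
  plots and ESS search over firing-rate grids.

## A worked example

Fifty random-firing attackers (`k_fire` = 50 firings cell⁻¹ h⁻¹) against
fifty strong retaliators ("2TFT", two aimed counterattacks per hit
sustained), mixed 1:1 in a 14-µm patch with resource quota 600 µm³:

```r
library(t6duel)
par <- sim_params(E_0 = 600, arena_radius = 14)
run <- compete(strategy_random(50), strategy_retaliator(2),
               params = par, n_each = 50, seed = 1)
run
#> T6SS competition run: 247 steps, t_end = 1.235 h
#>  genotype name n0       v0 n_end    v_end births deaths
#>         1    R 50 86.10123    53 112.7518     59     56
#>         2 2TFT 50 85.51740   136 328.4951    159     73
final_proportion(run, "2TFT")     # 0.72
strategist_fitness(run, "2TFT")   # 1.346
strategist_fitness(run, "R")      # 0.270
```

The patch ran for 247 steps (1.24 h) until the resource quota was gone.
Although the retaliators absorbed more deaths (73 vs 56) — they always get
stabbed first — their aimed double counterattacks killed enough attackers,
and their silence against non-aggressors saved enough growth, that they
finished with 72% of the cells and a five-fold higher invasion fitness
(`ω` is the log of the final-to-initial biovolume ratio). Swap in
`strategy_retaliator(1)` (classic tit-for-tat) and the same contest reverses
— single counterattacks cannot pay back the first-strike advantage.

Strategy constructors: `strategy_random(k_fire)`, `strategy_unarmed()`,
`strategy_retaliator(multiplicity, aiming, cost_saving)`,
`strategy_cheater()`. Preset experiment grids (density sweeps, retaliator
comparisons, the 2×2 aiming/cost-saving knockout grid) live in
`preset_sweep()`; fitness tables and invasion indices in
`simulate_fitness_table()`, `local_invasion_index()`,
`global_invasion_check()`, `mutual_immunity_indices()`,
`relatedness_indices()`, `cheater_triplet()`, `pairwise_invasion_plot()`
and `find_ess()`. A thin command-line wrapper is installed at
`inst/cli/t6duel` (`simulate`, `sweep`, `assay` subcommands over YAML
configs). The methods vignette (`vignettes/t6ss-warfare-model.Rmd`)
documents the model, its assumptions and every default.

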