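# smfsid

Classification and Bayesian identification of membrane proteins from AFM
single-molecule force spectroscopy (SMFS) force–distance curves.

## The problem

When an AFM tip pulls a single membrane protein out of a **native** membrane,
the retraction force–distance (F–D) curve shows a sawtooth of worm-like-chain
(WLC) branches, one per unfolding intermediate. In a native patch the protein
under the tip is unknown, the mixture composition is unknown, and the vast
majority of curves are spurious (no attachment, multiple attachments,
tethers). `smfsid` implements the full desk-side analysis for this setting,
for biophysicists working with SMFS data from native membranes:

1. **Preprocessing / coarse filtering** — baseline zeroing, tip–sample
   separation transform (`s = z − F/k`), interpolation on a 1-nm grid,
   rejection of traces without a contact point, with forces beyond 5000 pN,
   or with wavy tails (> 2 σ_NOISE).
2. **WLC quality score** — each point is transformed to a contour length by
   solving \( F(x) = \frac{k_B T}{l_p}\left[\frac14 (1-x/L_c)^{-2} - \frac14
   + x/L_c \right] \) for \(L_c\) (valid for 30–500 pN, \(l_p = 0.4\) nm);
   the Lc histogram (8-nm bins) is scored per peak with
   \(W = e^{-2f^2}\), \(f = \tfrac12(P_\mathrm{left}/P_\mathrm{max} +
   P_\mathrm{right}/P_\mathrm{max})\), and traces whose score-to-length
   ratio falls below 0.5 are discarded.
3. **Pairwise distances** — dynamic-programming global alignment of force
   profiles with the bounded match/mismatch score (scale
   \(F_\mathrm{scoring} = 4\sigma_\mathrm{NOISE}\)), giving
   \(d_{ab} = 1 - SD(N_a, N_b)/N_\mathrm{max}\).
4. **Density-peak clustering** — \(\rho_i = -\log r_{k,i}\) (quality
   weighted), \(\delta_i = \min_{j:\rho_j>\rho_i} d_{ij}\), centers chosen by
   descending \(\gamma = \rho\,\delta\) subject to a separation of
   \(r_\mathrm{cut} = 0.3\).
5. **Refinement and merging** — an "area of similarity" (5 nm × 5 pN cells)
   built from each center and its two nearest neighbours scores every curve;
   a slope-change threshold selects members and clusters sharing > 40 % of
   their members merge.
6. **Bayesian identification** — for each cluster, every protein A in a
   proteome table is scored by
   \(P(\mathrm{Prot_A}\mid C_X) \propto P(L_{c,\max}\mid L_{c,A})\,
   P(\bar F \mid \mathrm{structure}_A)\, P(\mathrm{peaks}\mid
   \mathrm{loops}_A)\, P(\mathrm{Prot_A})\), with the prior
   \(\mathrm{abundance}_A \times \mathrm{ismembrane}_A\), a Gaussian length
   likelihood centred at \(0.89\,L_{c,A}\) (relative width 0.10, switching
   to a uniform over the terminal-domain span when that domain is long), a
   per-secondary-structure force density, and the lag-bounded (±15 nm)
   cross-correlation between the cluster's Lc peak profile and Gaussian
   bells (FWHM 15 nm) at the protein's loop centers.

A synthetic-curve simulator (WLC sawtooths from protein templates, plus
spurious multi-attachment and tether traces, abundance-weighted mixtures and
matched synthetic proteome tables) makes the whole pipeline testable with no
instrument data.

## Worked example

```r
library(smfsid)

templates <- smfs_templates()                       # 3 distinct unfolding patterns
sim <- simulate_dataset(templates, c(1, 1, 1), 150,
                        sim_config(seed = 42, premature_detach_fraction = 0))
proteome <- synth_proteome(templates, n_decoys = 17, seed = 42)
run <- run_smfs_pipeline(sim$curves, proteome)
```

```
pipeline: 150 curves ingested, sigma_NOISE = 10.05 pN
  block 1: kept 150, rejected 0 ()
  block 2: 150 of 150 traces pass the quality cut
  block 3: 3725 of 11175 pairs computed
  block 4: 8 centers, 150 traces assigned
  block 5: 3 refined clusters
  identification: 3 clusters scored against 20 proteins
```

```r
run
#> SMFS pipeline run
#>   ingested 150 | block1 kept 150 | quality kept 150 | clusters 3
#>   top candidates:
#>     curve_0060 -> T3 (p = 1.000)
#>     curve_0061 -> T1 (p = 0.992)
#>     curve_0070 -> T2 (p = 0.999)

tidy(run$refined)
#> # A tibble: 3 × 4
#>   cluster_id n_members lc_max mean_force
#>   <chr>          <int>  <dbl>      <dbl>
#> 1 curve_0061        52    132      102.
#> 2 curve_0060        44    308      177.
#> 3 curve_0070        41    220       93.1
```

The three refined clusters recover the three generating templates: sizes
(52/44/41) are balanced as simulated, `lc_max` is the contour length of each
cluster's last unfolding barrier (templates end at 130, 310 and 219 nm), and
each cluster's posterior puts essentially all mass on its generating template
despite the 17 decoy proteins. `autoplot(run$clustering)` draws the
density-peak decision graph; `plot_posteriors(run$posteriors)` shows the
ranked candidates; `write_results()` exports member lists, cluster summaries
and per-cluster candidate tables as TSV.

A thin command-line wrapper (`inst/cli/smfsid.R`) exposes `simulate` and
`run-all` subcommands over the same functions.

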