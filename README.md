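# ppicore

Protein complexes leave a characteristic footprint in protein–protein
interaction (PPI) networks: a small, densely interacting **core** that
carries the complex's essential function, surrounded by looser **attachment
proteins** — *peripheral* proteins that belong to a single complex and
*overlapping* proteins shared between several complexes. `ppicore`
identifies complexes from a plain edge list by exploiting exactly this
core-attachment organisation, and ships the standard evaluation metrics, a
hypergeometric enrichment test, and a planted-complex network simulator for
benchmarking. It is aimed at systems-biology researchers who want a
transparent, scriptable complex-detection pipeline for yeast- or human-scale
interactomes.

## Method

1. **Edge reliability weighting.** High-throughput PPI data is noisy, so
   each edge `(v, u)` is scored from topology alone. With `N(v)` the
   neighbour set and `CN(v,u) = N(v) ∩ N(u)`:

   - Jaccard coefficient similarity
     `JCS(v,u) = |CN(v,u)| / |N(v) ∪ N(u)|` (0 without common neighbours);
   - common-neighbour support
     `CNS(v,u) = Σ_{w ∈ CN(v,u)} JCS(v,w) · JCS(w,u)`;
   - high-order common-neighbour weight
     `HOCN(v,u) = (JCS(v,u) + CNS(v,u)) / (|CN(v,u)| + 1)`.

   Edges whose endpoints share no common neighbour are discarded as
   unreliable.

2. **Core mining.** Every vertex `v` seeds a preliminary core containing
   each neighbour `w` whose structural similarity
   `SS(v,w) = |SN(v) ∩ SN(w)| / sqrt(|SN(v)|·|SN(w)|)` (closed
   neighbourhoods `SN(v) = {v} ∪ N(v)`) reaches a threshold `ss`
   (default 0.4). Cores below two members are dropped; duplicates collapse.

3. **Attachment classification.** A protein with ≥ 2 weighted edges into a
   core is a candidate attachment. It is *overlapping* when
   `weight_out ≥ weight_in` and `weight_in ≥ weight_avg(core)/2`, and
   *peripheral* when `weight_in > weight_out` and `weight_in` is at least
   the candidate-set average.

4. **Assembly.** Complex = core ∪ attachments; complexes smaller than 3 and
   exact duplicates are removed.

Predicted sets are scored against a reference catalogue by
neighbourhood-affinity (`NA(A,B) = |A∩B|²/(|A||B|)`) recall, precision and
F-measure (match threshold `t = 0.2`), coverage rate, the maximum matching
ratio (maximum-weight one-to-one matching of reference to predicted
complexes), and per-complex hypergeometric enrichment p-values.

## Worked example

The 11-protein toy network pins down the weighting arithmetic by hand:

```r
library(ppicore)
net <- toy_ppi_network()
jaccard_similarity(net, "b", "d")
#> [1] 0.2222222        # = 2/9
hocn_weight(net, "b", "d")
#> [1] 0.1025132        # = (2/9 + 1/72 + 4/56) / 3, i.e. 0.102 at 3 decimals
```

End-to-end on a simulated benchmark with five planted complexes:

```r
sim <- simulate_ppi(seed = 42)          # planted core-attachment network
res <- detect_complexes(sim$edges, ss = 0.4)
glance(res)
#> # A tibble: 1 × 9
#>   n_complexes n_proteins mean_size n_multi_complex n_input_edges ...
#> 1          23         38      8.87              38           146
evaluate_complexes(res, sim$truth)
#> # A tibble: 1 × 8
#>   recall precision f_measure coverage_rate   mmr n_pred n_ref na_threshold
#> 1      1         1         1             1     1     23     5          0.2
```

All five planted complexes are recovered (recall 1), every emitted complex
matches a planted one (precision 1), and the maximum matching ratio of 1
shows a perfect one-to-one correspondence between the best five predictions
and the planted truth. `tidy(res)` breaks each complex into core /
peripheral / overlapping member counts, and `autoplot(res)` draws the
composition. `sweep_ss()` re-runs the pipeline over a threshold grid to
expose the precision–recall trade-off in `ss`.

A command-line interface is installed as `exec/ppicore` with subcommands
`weight`, `detect`, `evaluate`, `enrich`, `simulate` and `sweep`:

```sh
Rscript exec/ppicore detect --in edges.txt --out complexes.txt --ss 0.4
```

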