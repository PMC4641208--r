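---
title: "Multicriteria protein structure comparison: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicriteria protein structure comparison: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpsc)
```

## The problem

No single protein structure comparison (PSC) method is accepted as uniformly
best: compression-based metrics, TM-score-style aligners and RMSD-based
aligners emphasize different aspects of structural similarity and disagree on
real data. The pragmatic response in the field is *multicriteria* PSC: score
every pair of domains with several methods and fuse the per-method scores
into one consensus dissimilarity per pair. Because an all-to-all run over
$K$ domains with $M$ methods generates $K^2 \cdot M$ independent jobs whose
costs vary by orders of magnitude, the computation is also a scheduling
problem, and this package treats it as one.

The package provides the full chain: PDB C-alpha parsing, contact maps, three
built-in pairwise methods, consensus scoring, job-farm partitioning and
simulation, average-linkage clustering, and F-measure evaluation, plus a
synthetic-data module so every stage is testable without downloads.

## Pairwise methods

**Compression distance (`usm`).** The Kolmogorov complexity of a domain is
approximated by the gzip-compressed size of a canonical serialization of its
contact map (residues $i<j$ with C-alpha distance $\le 8$ Å and sequence
separation $\ge 2$; both parameters configurable). For serializations $x, y$
the score is the normalized compression distance

$$\mathrm{NCD}(x,y) = \frac{C(xy) - \min(C(x), C(y))}{\max(C(x), C(y))},$$

with $xy$ the concatenation in byte-lexicographic order, which makes the
value exactly symmetric. This equals the universal similarity metric
$\max\{K(x|y),K(y|x)\}/\max\{K(x),K(y)\}$ under the standard approximation
$K(x|y) \approx K(xy) - K(y)$. The compressor is R's `memCompress` gzip
path; it exposes no level parameter, so sizes (and hence values) are fixed
per compressor build. Self-distances are not exactly zero — compressor
redundancy leaves a residual, empirically $\approx 0.06$ and bounded at
$0.15$ in the tests; two unrelated random maps score $\approx 0.9$.

**TM-score-like similarity (`tm`) and RMSD (`rmsd`).** These are explicit
stand-ins for external aligners such as TMalign and CE, not
re-implementations: the residue correspondence comes from a global
Needleman–Wunsch alignment (match 1, mismatch 0, gap $-1$; deterministic
diagonal-then-up-then-left traceback) rather than from a
sequence-independent structural search. Given the correspondence, the
superposition is refined iteratively: superpose (Kabsch, proper rotation) on
the current subset, keep corresponded pairs within $2 d_0$, repeat to
convergence (max 20 iterations), starting from the full correspondence and
from fragments of length $L/2$ and $L/4$ at each quarter offset; the start
with the highest score wins. The score is

$$\mathrm{TM} = \frac{1}{L_{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2},
\qquad d_0 = \max\!\big(0.5,\; 1.24\,(L_{ref}-15)^{1/3} - 1.8\big),$$

normalized by the length $L_{ref}$ of the second (database) domain; the
0.5 Å floor handles short domains (at $L_{ref}=21$ the raw value
$\approx 0.453$ is floored). One alignment pass per pair feeds both the
`tm` similarity and the `rmsd` distance (RMSD over the final kept pair
set), so the parallel farm performs $M = 2$ structural computations per
pair. An adapter (`load_external_scores`) ingests TSVs of real external
aligner scores so they can replace the stand-ins in the consensus.

## Consensus

Scores are collected into a $P \times M$ matrix ($P$ pairs). Similarity
columns are inverted ($1 - s$; only defined for $[0,1]$-bounded
similarities), every column is min-max scaled,

$$X'_{i,j} = \frac{X_{i,j} - \min_i X_{i,j}}{\max_i X_{i,j} - \min_i X_{i,j}},$$

and the consensus is the row mean, so 0 is most similar. Normalization is
global over the run's $P$ rows. Design points: similarities are inverted
*before* scaling (ranks are preserved either way for $[0,1]$ similarities);
a degenerate column ($\max = \min$) becomes all zeros — that method sees all
pairs as equally similar and should contribute no discrimination rather than
divide by zero; raw RMSD enters in Å because min-max scaling absorbs any
positive affine change of units (a property the tests assert).

## Scheduling

`generate_jobs` builds the $K_Q \times K_D$ farm per method, self-pairs
included. Fast methods (the compression distance by default) are routed
`sequential` and run in the coordinator; the rest are dispatched to workers.
Since wall-clock times cannot anchor tests, scheduling is simulated with
explicit per-job costs. Job cost is modeled as a polynomial in a length
attribute — the sum or product of the pair's lengths — because pairwise
alignment time grows with both lengths; on data generated from a quadratic
product-attribute model the refit recovers coefficients exactly and the
quadratic fit never loses to the linear one (nested least squares).

Three strategies are implemented, all fully deterministic (sorting ties by
job ids, running-sum and next-free ties by lowest index):

* `partition_random` — equal-count partitions after a seeded shuffle;
* `partition_greedy_lpt` — longest-processing-time greedy on the attribute;
* `sort_jobs_desc` + `dispatch_round_robin` — descending presort, then
  event-driven next-free dispatch (the dynamic task farm).

The simulator reports per-worker finish times, makespan, speedup (serial
time / makespan) and efficiency (speedup / workers). On simulated quadratic
costs over a 34-domain, 47-worker configuration the mean makespan ordering
is sorted round-robin $\le$ greedy LPT $\le$ random, and LPT stays within
the classical $(4/3 - 1/(3N))$ factor of the brute-force optimum on small
instances — both asserted in the acceptance suite.

## Evaluation

Directed consensus scores are symmetrized by averaging the two directions
(the compression distance is symmetric by construction; the aligner
stand-ins are near-symmetric), the diagonal is forced to zero, and the
matrix is clustered with unweighted average linkage (UPGMA). The
agglomeration is implemented in-package because deterministic tie-breaking
(lexicographically smallest representative-id pair) is part of the
contract; `stats::hclust` serves as an independent oracle in the tests, and
merge-height monotonicity is asserted on generated fixtures (average
linkage admits no inversions there, though that is not a general theorem).
The tree is cut by count to $C$ clusters ($C = 5$ for the benchmark
emulation, undoing the last $C-1$ merges).

Cluster quality uses the F-measure: each cluster maps to its majority true
class (ties to the class of the lexicographically smallest member id — the
mapping rule is our documented choice, as the literature leaves it to a
citation), TP are members of the mapped class, FP the rest, FN the mapped
class's members outside the cluster; then $P = TP/(TP+FP)$,
$R = TP/(TP+FN)$, $F = 2PR/(P+R)$. With majority mapping over a partition,
$TP + FP = K$.

## The synthetic world

`make_benchmark` emulates a small fold-classification benchmark: families
are deterministic template backbones — ideal $\alpha$-helix (rise 1.5 Å,
turn 100°, radius 2.3 Å), extended zigzag strand (step 3.3 Å), or a mixed
helix+strand chain, with perturbed turn angles / steps when more families
than geometries are requested — and members are the template under a random
rigid transform, i.i.d. Gaussian coordinate noise, and random single-residue
deletions. Defaults and why:

* **5 families × 7 members, length 60** — mirrors the fivefold-family
  structure of the classic 34-domain benchmark at a desk-scale length that
  keeps the full pipeline under a minute;
* **noise_sd 0.3 Å** — the stated clean-benchmark condition; it leaves
  within-family TM-scores above 0.9 while between-family scores stay below
  0.5;
* **indel_rate 0.05** — enough to exercise alignment gaps without breaking
  family coherence (must stay below 0.2);
* **scheduling simulation** — 34 domains with lognormal lengths clamped to
  [90, 500] Å (median near 150, matching the published benchmark's length
  statistics), quadratic product-attribute costs with log-normal noise
  (sd 0.25), 47 workers.

What the generator does **not** emulate: real backbones (no Ramachandran
sampling, no side chains), sequence divergence within families (members
share the template sequence minus deletions, so the sequence-guided
correspondence is easier than in remote homologs), and realistic
contact-map topology beyond what the idealized geometries induce. A green
end-to-end test therefore establishes that the pipeline's machinery is
correct and that the ensemble property holds on separable data — not that
the stand-in aligner matches external tools on real proteins. Reproducing
published F-measures on the real 34-domain set would require the original
structures and external aligner scores via the adapter path, and is out of
scope.

All generators are pure functions of (spec, seed) with isolated RNG
streams; no function perturbs the caller's `.Random.seed`.

## Numerical choices and degenerate inputs

* Compressor self-distance is clamped at zero; a zero-size compressor
  output raises an internal error.
* Kabsch handles rank-deficient cases by the standard determinant
  correction (det $= +1$ always); superposition of identical sets returns
  identity rotation and zero translation.
* Refinement keeps a minimum of 3 pairs; if a step drops below that, the
  full-correspondence superposition is the fallback.
* Degenerate normalization columns become zeros (see above); empty score
  sets are errors, not empty results, except the documented header-only TSV
  round trip.
* `cut_to_k` requires $1 \le C \le K$; `hclust_average` requires $K \ge 2$.

## Known limitations

* The `tm`/`rmsd` stand-ins are sequence-guided; structurally similar but
  sequence-divergent pairs score lower than a true structural aligner
  would. Use the external-score adapter for real analyses.
* UPGMA is $O(K^3)$ in plain R; fine for hundreds of domains, not for
  thousands.
* The worker pool uses forked processes (`parallel::mclapply`); on
  platforms without fork the farm runs in-process, with identical results
  by the determinism contract.
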