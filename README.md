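# tdanull: a universal null distribution for persistence diagrams

Persistent homology summarises the multiscale shape of a point cloud as a
persistence diagram: a multiset of (birth, death) scale pairs, one per
topological feature (loops, cavities, ...). The hard statistical question is
which of those features are *signal* — latent structure of the sampled space
— and which are *noise* thrown up by sampling randomness.

`tdanull` implements a hypothesis-testing framework built on a striking
empirical regularity: for a noise feature with persistence ratio
π = death/birth, the transformed value

    ℓ = A·log log π + B,   A = 1 (Rips) or 1/2 (Čech),
    B = −λ − A·L̄,          L̄ = mean of log log π over the diagram,

follows the **left-skewed Gumbel law** F(x) = 1 − exp(−exp(x)) regardless of
the sampled space, the sampling distribution, the filtration, or the
homology degree (λ = 0.5772156649… is the Euler–Mascheroni constant, the
magnitude of the law's mean). Treating that law as the null gives each
feature a p-value

    p = exp(−exp(ℓ)),

and a Bonferroni correction at level α/|dgm| extracts the signal features.
Cycles still alive at a computation threshold τ ("infinite" cycles) only
admit the bound π > τ/b; an iterative threshold search raises τ just far
enough to decide each of them — typically far below the cycle's actual
death scale, which is what makes the test tractable for large complexes.

The package provides:

* **Samplers** (`samplePointCloud`, `sampleEight`, `delayEmbed`,
  `sampleMesh`) for the full battery of synthetic models used to probe the
  null law: box, ball, annulus, sphere, beta/normal/Cauchy products, torus,
  Klein bottle, projective plane, pentagon-linkage configuration spaces,
  Henneberg surface, stratified plane-in-cube, Brownian paths, Lorenz
  trajectories, mesh surfaces, time-delay embeddings, and a noisy
  figure-eight. All are seedable and reproducible.
* **Persistence** (`computeDiagram`) via a built-in engine: Vietoris–Rips
  (any dimension, point clouds or distance matrices) and Čech filtrations
  on a unified radius scale, with an alpha-complex fast path for planar
  clouds and a self-contained boundary-matrix-reduction oracle
  (`naiveRipsPersistence`) for correctness checks.
* **The universal-null toolkit** (`piValues`, `ellTransform`, `plgumbel`,
  `ksGof`, `ecdfQq`) and the tests themselves (`signalFeatures`,
  `findInfiniteThreshold`, `fullReport`).
* A **command line** (`inst/scripts/tdanull`) wiring the pieces into
  `sample`, `diagram`, `transform`, `diagnose`, `test`, `infinite` and
  `demo-eight` subcommands with JSON manifests for reproducibility.

## Worked example

One thousand points on a figure-eight whose lobes meet at a neck of width
W = 0.1; both loops should be (and are) detected:

```r
library(tdanull)
pc  <- sampleEight(1000, W = 0.1, seed = 1)
dgm <- computeDiagram(pc, "cech", maxDegree = 1)
rep <- signalFeatures(dgm, k = 1, alpha = 0.05)
cat(renderReport(rep, max.rows = 4))
```

```
H1 cech filtration, alpha=0.05, m=375, Bonferroni level 0.000133
     birth      death        pi p-value
   0.03627    0.97533     26.89 3.601e-05  *
  0.049623    0.97067     19.56 5.98e-05  *
  0.011655   0.018127     1.555 0.02357
  0.011244   0.016762     1.491 0.02834
```

The two rows flagged `*` are the outer loop and the neck loop: their
persistence ratios (19–27) sit far outside the null and their p-values
clear the Bonferroni level 0.05/375, while the remaining noise loops
(ratios near 1.5) land where the left-skewed Gumbel law predicts. Widening
the neck to `W = 0.4` (same seed) leaves only the outer loop significant:
the neck loop's ratio drops to 4.9, p = 0.0017 — small, but not small
enough to survive a 372-way correction.

The same verdict logic drives `findInfiniteThreshold()`, which decides
cycles that are still alive at the computation threshold by raising the
threshold to each cycle's own certification point `b · π_min(α/|D|)`
instead of chasing its death scale.

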