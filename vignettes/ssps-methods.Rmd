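---
title: "Model and methods behind ssps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind ssps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssps)
```

## The inference problem

`ssps` infers a directed graph over a set of measured variables — in the
motivating application, phosphosites in a signaling pathway — from short,
replicated time courses. An edge $i \to j$ means that the level of variable
$i$ at time $t-1$ linearly influences variable $j$ at time $t$: the model is
a linear-Gaussian Dynamic Bayesian Network (DBN), so edges always run across
one time step and cycles in the summary graph (including self-edges, which
are plain autoregression) are legitimate.

The data are typically tiny — a handful of replicate courses of fewer than
ten timepoints — so the likelihood alone cannot pin down a graph over dozens
of variables. Two ingredients make the problem workable:

* **prior edge confidences** $c_{ij} \in [0,1]$, usually curated from
  pathway databases, which concentrate the posterior around biologically
  plausible graphs; and
* **full marginalization of the regression parameters**, which turns the
  posterior into a distribution over discrete structures (plus one
  continuous nuisance scalar per vertex) that MCMC can traverse.

## The model

For vertex $j$ with parent set $pa(j)$, stack the response
$y_j$ (variable $j$ at timepoints $2..T_m$ of every course) and the design
$B_j$ (the parents at timepoints $1..T_m-1$). With $n = \sum_m (T_m - 1)$
pooled transitions we define the *effective timepoint count* $T = n + 1$,
which reduces to the plain course length when there is a single course.
Under a conditional Gaussian likelihood, a $g$-prior-style coefficient
prior with scale $T$, and the improper $1/\sigma_j^2$ variance prior, the
coefficients and variances integrate out in closed form. Up to constants
shared by all parent sets of vertex $j$:

$$
\log P(y_j \mid pa(j)) =
-\frac{|pa(j)|}{2}\log T
-\frac{n}{2}\log\!\Big(y_j'y_j - \tfrac{n}{n+1}\, y_j'B_j\hat\beta\Big),
$$

with $\hat\beta$ the (minimum-norm) OLS solution. Each extra parent costs
$\tfrac12\log T$ before it explains any variance — the automatic Occam
penalty that favors sparse graphs. In-degrees are *not* capped: when a
parent set outgrows the sample size the OLS step switches to the
Moore–Penrose pseudo-inverse, and the projection identity
$y'B\hat\beta \le y'y$ keeps the log argument non-negative.

The structure prior treats every potential edge as an independent
Bernoulli draw,

$$
P(z_{ij} = 1 \mid c_{ij}, \lambda_j)
= \frac{e^{-\lambda_j}}{e^{-c_{ij}\lambda_j} + e^{-\lambda_j}},
$$

so a fully trusted edge ($c_{ij}=1$) is a fair coin flip, an unsupported
edge ($c_{ij}=0$) has probability $\approx e^{-\lambda_j}$, and fractional
confidences interpolate. With binary confidences this reproduces, exactly
and in normalized form, the classical reference-graph prior that penalizes
each edge outside the reference by $e^{-\lambda}$ (the package tests verify
this by exhaustive enumeration of all two-vertex graphs). The per-vertex
inverse temperature $\lambda_j \sim \mathrm{Uniform}(\lambda_{\min},
\lambda_{\max})$ lets each vertex learn how much to trust its prior column;
a shared $\lambda$ tends to get trapped between modes.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda_min` | 3 | floor of the $\lambda_j$ prior; values near 0 initialize chains with huge edge counts |
| `lambda_max` | 15 | ceiling of the $\lambda_j$ prior; results are insensitive once it is comfortably large |
| `xi` | 3 | SD of the Gaussian random walk on $\lambda_j$; the sampler is insensitive to it |
| `chains` | 4 | independent chains for the split-chain diagnostics |
| `max_iterations` / `max_hours` | 100 000 / 12 | termination: whichever comes first, mirroring an overnight run |
| `burnin` | 0.5 | fraction of each chain discarded before summarization |
| `standardize` | `TRUE` | center/scale each variable's pooled column before inference |
| `allow_self_edges` | `TRUE` | keep lagged autoregressive edges in the candidate set |

## The sampler

One iteration sweeps the vertices in ascending order; for each vertex a
Metropolis–Hastings update of $\lambda_j$ (prior-only, since the likelihood
does not involve $\lambda_j$) is followed by one parent-set move. The
parent-set proposal draws one of three actions — **add** a uniformly chosen
non-parent, **remove** a uniformly chosen parent, or **swap** one of each —
with probabilities built from $u = (s/|V|)^{\gamma(\hat s)}$,
$\gamma(\hat s) = 1/\log_2(|V|/\hat s)$, where $s$ is the current parent
count and $\hat s_j = \sum_i c_{ij}$ the prior-implied reference size:
unnormalized weights $(1-u,\; u,\; 2u(1-u))$. At $s=0$ add is certain, at
$s=|V|$ remove is certain, and at $s=\hat s$ all three actions are equally
probable, steering the chain toward parent sets of plausible size. Swap
moves matter because the $\tfrac12\log T$ penalty makes size-preserving
updates much easier to accept than size-changing ones. Each action is
paired with its exact reverse (add↔remove at the neighboring size; swap is
self-inverse), giving the reverse-transition mass in closed form.

Numerical and bookkeeping choices:

* $\hat s_j$ is clamped to $[1, |V|/2]$ so the exponent
  $\gamma$ is defined for empty or overfull prior columns.
* The likelihood's log argument is floored at $10^{-12}\, y'y$ to guard
  floating-point cancellation in interpolating fits.
* Per-vertex likelihoods are evaluated from cached cross-product matrices
  ($X'X$ Gram blocks), so each proposal costs one $s \times s$ solve
  regardless of $|V|$ or the number of timepoints.
* Chains are initialized overdispersed: $\lambda_j \sim
  U(\lambda_{\min}, \lambda_{\max})$ and each edge drawn from its prior
  Bernoulli probability at that $\lambda_j$.
* Traces are delta-encoded (initial state plus accepted changes per
  iteration) — the representation that keeps memory proportional to the
  acceptance rate rather than to $|V|^2 \times$ iterations. Replaying
  deltas reconstructs any intermediate state exactly, and the tests check
  this against dense storage.
* Chain $k$ is seeded with `base_seed + k`; identical inputs and seed give
  a bit-identical trace.

## Diagnostics and summarization

After discarding the first half of each chain (configurable), the posterior
probability of edge $i \to j$ is the pooled frequency of samples containing
it. Convergence is monitored per edge-indicator sequence and per
$\lambda_j$ sequence:

* **PSRF** (potential scale reduction factor), split-chain variant: each
  chain is halved and the between/within variance ratio computed over the
  half-chains. A quantity fails at PSRF ≥ 1.01.
* **Effective sample size**, multi-chain, with Geyer's initial monotone
  positive-sequence truncation of the autocorrelation sum. A quantity
  fails below 10 effective samples.

Binary indicator sequences are frequently constant, where both formulas are
0/0. The conventions: all chains constant and equal → PSRF 1 and ESS equal
to the total retained draws (the quantity is trivially converged); chains
constant but disagreeing → PSRF $\infty$ and ESS equal to the chain count.
Passing these checks does not prove convergence; failing them reliably
flags non-convergence.

## The synthetic benchmark

The generator emulates the structure of the real phosphoproteomic task
while staying inside the model class. Per instance: adjacency entries are
independent Bernoulli$(5/|V|)$ (five parents per vertex on average, the
sparsity expected of pathways), weights on edges are $N(0, 1/|V|)$ (a scale
that keeps the linear dynamics from diverging), and $M=4$ courses of
$T=8$ timepoints evolve as $x_{t+1} = \beta' x_t + \varepsilon$ with
$x_1 \sim N(0, I)$ and unit innovation variance (the generator specifies
weights; initial state and noise scales are the package's choice of a
standard unit-scale setting). The prior handed to inference is the true
adjacency *corrupted*: a fraction $r$ of true edges removed and $a\,|E_0|$
spurious edges added (rounding half-to-even), modelling false negatives
and false positives in curated knowledge. The full grid crosses
$|V| \in \{40, 100, 200\}$ with $r, a \in \{0.1, 0.5, 0.75, 1.0\}$ — 48
cells, 5 replicates each, 240 instances.

What the generator does *not* emulate: real phosphorylation intensity
distributions, missing values, measurement-technology artifacts, latent
(unphosphorylated) pathway members, or nonlinear regulation. Passing the
benchmark therefore shows the estimator works when its assumptions hold —
a sanity check, not evidence about any particular biological dataset.

## Evaluation metrics

Edge recovery is scored by **AUCPR via average precision**
($\sum_k \Delta R_k P_k$ over descending score blocks; tied scores enter as
one block), the right area for needle-in-a-haystack tasks where positives
grow linearly but candidates quadratically; trapezoidal PR interpolation is
deliberately avoided as optimistic. Self-edges are part of the task by
default (they are modelled), with a masking flag. The **prior baseline**
scores the confidence matrix itself as a prediction — a Bayesian method
should beat its own prior when the data carry signal — and per-cell
**paired t-statistics** ($t = \bar d / (s_d/\sqrt K)$, $\pm\infty$ at zero
variance by convention) summarize the comparison. For interventional gold
standards, **descendant-set AUCROC** thresholds the edge probabilities,
takes graph reachability from a source vertex, and integrates the
resulting ROC by the trapezoidal rule; the **dominance** relation (minimum
of the stochastic method's repeat scores versus a deterministic score)
summarizes repeat runs strictly.

## Problem sizes used in the shipped tests

The package's own validation runs at desk scale, chosen so the full suite
completes in minutes: exact-posterior recovery enumerates all parent sets
at $|V|=3$ (fixed $\lambda$, where the posterior factorizes per vertex) and
compares 4 chains × 8 000 iterations against it within three Monte-Carlo
standard errors; the prior-improvement check runs five $|V|=40$, $r=a=0.1$
instances at 2 chains × 1 000 iterations; the mixing comparison against a
uniform-toggle baseline uses $|V| \in \{20, 40\}$ at 600 iterations,
scoring ESS of the per-vertex parent-count series (per-edge indicator ESS
is saturated by the constant-sequence convention on never-touched edges,
which would mask the difference). Production runs should use the default
termination policy.

## Known limitations

* The linear-Gaussian DBN excludes nonlinear and contemporaneous effects;
  unobserved regulators are silently absorbed into noise.
* Posterior edge probabilities are only as good as chain mixing; always
  inspect the per-edge convergence flags before interpreting small
  probability differences.
* The $\lambda$ bounds are a pragmatic prior: with totally uninformative
  confidences the model leans on sparsity alone, and with adversarially
  wrong priors ($r = 1$) performance degrades by design — the method is
  built for *partially* accurate prior knowledge.
* Runtime grows linearly in $|V|$ per sweep, but mixing time grows too;
  for problems far beyond a few hundred variables, prune to the most
  variable measurements first.
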