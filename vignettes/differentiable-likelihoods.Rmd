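---
title: "Differentiable phylogenetic likelihoods: model, gradients, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable phylogenetic likelihoods: model, gradients, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodiff)
```

## The model

Residue substitution in an alignment column is modelled as a
continuous-time Markov chain over $n$ states ($n = 4$ nucleotides or
$n = 20$ amino acids), specified by a rate matrix $Q$ with non-negative
off-diagonal entries and zero row sums.  The probability of observing
state $b$ a time $t$ after state $a$ is $(e^{Qt})_{ab}$, with $t$
measured in expected substitutions per site.  Given a rooted tree with
branch lengths and residue profiles at the leaves, Felsenstein's pruning
recursion computes the column log likelihood by marginalizing all
ancestral states in one post-order sweep.

`phylodiff` assumes time reversibility: there is a distribution $\pi$
with $\pi_i q_{ij} = \pi_j q_{ji}$.  The package parametrizes such
models by the $n(n-1)/2$ non-negative exchangeabilities $s_{ij}$ — the
upper triangle of the symmetrized generator
$S = \mathrm{diag}(\sqrt{\pi})\, Q\, \mathrm{diag}(\sqrt{\pi})^{-1}$ —
and the positive vector $\sqrt{\pi}$, so that
$q_{ij} = s_{ij}\sqrt{\pi_j}/\sqrt{\pi_i}$ with the diagonal fixed by
the zero row sums.  Two consequences drive the whole design:

* $S$ is symmetric, so $Q$ has a *real, numerically stable*
  eigendecomposition $Q = A \Lambda A^{-1}$ obtained from a symmetric
  eigensolver, with $A = \mathrm{diag}(\sqrt{\pi})^{-1} B$ and
  $A^{-1} = B^\top \mathrm{diag}(\sqrt{\pi})$ — no general eigensolver
  and no matrix inversion are ever needed;
* every transition matrix on the tree is then two matrix products,
  $P(t) = A\, e^{\Lambda t} A^{-1}$: the decomposition is paid once per
  rate matrix and reused across all branches.

$\pi$ is *derived* from $\sqrt{\pi}$ by squaring and normalizing.
$\sqrt{\pi}$ itself is unconstrained positive: $Q$ and $\pi$ are
invariant under positive rescaling of $\sqrt{\pi}$, so no sum constraint
is imposed and gradients stay unconstrained (the gradient is exactly
orthogonal to the scale direction, which the test suite asserts).
Entries of $\sqrt{\pi}$ below $10^{-10}$ are clamped to $10^{-10}$ —
the transforms $A, A^{-1}$ blow up as a component approaches zero — and
clamped coordinates get gradient 0 (the clamp is flat, so this is the
natural subgradient choice).

## Stable gradients of the matrix exponential

Differentiating through an eigendecomposition directly is numerically
treacherous: eigenvector derivatives blow up as eigenvalues coalesce.
The package avoids that entirely.  For a direction $\partial Q$, the
derivative of the matrix exponential in spectral form is

$$
\frac{\partial e^{Qt}}{\partial \theta}
 = A \left( A^{-1} \frac{\partial Q}{\partial \theta} A
   \odot X(\Lambda, t) \right) A^{-1},
\qquad
X(\Lambda,t)_{ij} =
\begin{cases}
 t\, e^{t\lambda_i} & i = j\\[2pt]
 \dfrac{e^{t\lambda_i} - e^{t\lambda_j}}{\lambda_i - \lambda_j} & i \ne j,
\end{cases}
$$

where $\odot$ is the elementwise product.  The divided difference in
$X$ is the only delicate quantity: the naive quotient loses all
significant digits when $\lambda_i \approx \lambda_j$.  Every entry of
$X$ is therefore evaluated through one symmetric formula

$$
X_{ij} = e^{t(\lambda_i+\lambda_j)/2}\; t\;
         \mathrm{sinch}\!\left(\tfrac{t(\lambda_i-\lambda_j)}{2}\right),
\qquad \mathrm{sinch}(z) = \frac{\sinh z}{z},\ \mathrm{sinch}(0)=1,
$$

which is continuous in the gap, reduces to the diagonal formula at exact
ties, and is accurate for every gap size (the suite checks it against an
independent `expm1`-based evaluation across gaps from $10^{-1}$ down to
$10^{-16}$, where the naive quotient visibly fails).  Below $|z| <
10^{-5}$ the $\sinh z / z$ ratio is replaced by its Taylor series to
keep full precision through the removable singularity; above
$t\,|\mathrm{gap}|/2 > 350$, where $\sinh$ would overflow, the plain
quotient is used instead — at such gaps it is exact to machine
precision, so this is purely an overflow guard, not an accuracy switch.
$t = 0$ needs no special case: $X(\Lambda,0) = 0$ and $P(0) = I$ emerge
from the general path.

A likelihood has one scalar output and many parameters (a per-column
20-state model has 209 free quantities per column), so reverse mode is
the right differentiation direction: instead of pushing every
$\partial Q/\partial\theta_u$ forward, one gradient
$\partial L / \partial e^{Qt}$ is pulled back through the *transpose* of
the Jacobian.  Writing the forward map above as a linear operator in the
perturbation and transposing it under the trace inner product
$\langle M, N\rangle = \mathrm{Tr}(M^\top N)$ gives

$$
\frac{\partial L}{\partial Q}
 = A^{-\top} \left( A^\top \frac{\partial L}{\partial e^{Qt}} A^{-\top}
   \odot X(\Lambda, t) \right) A^{\top},
$$

four matrix multiplications for any $t$ (`expm_adjoint()`).  The test
suite verifies the defining adjoint identity
$\langle J(M), N\rangle = \langle M, J^\top(N)\rangle$ to $10^{-10}$
over random models, times and directions at $n \in \{2, 4, 20\}$.
Because a tree contributes one such term per branch and all branches of
a model share $A$, the engine accumulates only the inner Hadamard factor
per branch (`expm_adjoint_inner()`) and applies the two outer
multiplications once per rate matrix.

## The forward and reverse passes

The forward pass keeps per-node partial likelihoods in log space and
combines children with logsumexp, so deep trees and small transition
probabilities cannot underflow; there is deliberately no scaling-factor
variant.  Leaves enter as non-negative profiles: one-hot for observed
residues, indicator profiles for IUPAC ambiguity codes (nucleotides) and
B/Z/X (amino acids), all-ones for gaps.  Profiles are indicators rather
than renormalized distributions, so a gap contributes a factor of
exactly 1, the standard pruning convention; arbitrary non-negative
profiles (e.g. basecall uncertainty) are equally accepted.

The reverse pass backpropagates through the logsumexp recursions in one
pre-order sweep, producing $\partial L/\partial P$ for every edge in
time linear in the number of nodes, then converts them to
$\partial L/\partial Q$ per model as above.  Branch-length gradients
come almost for free:
$\partial L/\partial t_e = \langle \partial L/\partial P(t_e),\,
Q P(t_e)\rangle$.  The root prior is the stationary distribution of the
column's model — the standard choice for reversible models and the one
consistent with exposing $\sqrt{\pi}$ as a parameter — and its
contribution $\partial L/\partial \pi$ is folded into the
$\sqrt{\pi}$ gradient through the squaring-and-normalizing chain rule.
Unrooted (trifurcating) input trees are rooted at the basal node; by
reversibility the likelihood is invariant to that choice, which the
suite asserts by re-rooting at random positions along branches (pulley
principle).  Multifurcations are accepted as-is, and columns mapped to
different models are processed as independent blocks, with all
column-wise work done as $n \times C$ matrix algebra so that the global
single-matrix case costs a handful of small dense products per edge
regardless of the column count.

Identical columns can optionally be collapsed to weighted patterns
(`compress_columns()`); weights multiply column log likelihoods and
gradients, leaving every result unchanged while shrinking realistic
alignments substantially.

## Fitting

`fit_model()` maximizes the total log likelihood with L-BFGS
(`stats::optim`, memory 10) over the log of every positive parameter —
log-reparametrization enforces positivity without box constraints and
matches the model's scale-invariance structure.  Three model kinds are
supported: one global matrix (`global_gtr`), a shared exchangeability
set with column-specific equilibria (`shared_S_column_pi`), and fully
independent per-column matrices (`per_column_gtr`).

Under rate normalization (default for the global model) $Q$ is rescaled
to mean rate $-\sum_i \pi_i q_{ii} = 1$ after each build and the
gradient is projected through the rescaling, rather than pinning one
coordinate; the exchangeability scale is thus absorbed into the branch
lengths, which is what makes the free-parameter count of the global
20-state model $190 - 1 + 19 = 208$.  For the column-specific kinds the
flag is ignored: rescaling each column's $Q$ separately would silently
redefine the shared $S$.

Optimization runs in outer rounds of up to 10 L-BFGS iterations and
stops when a round improves the log likelihood by less than $10^{-6}
\cdot |L|$ (0.0001 %), the convergence policy this package adopts; since
the rule is applied per round rather than per iteration it can only stop
later than a per-iteration check, never earlier.  An optional L2 penalty
on the log-parameters is available (a penalty of exactly 0 takes the
unpenalized code path bitwise).  Seeds influence only an optional
initialization jitter; the optimization itself is deterministic.

## The simulator

Test data are generated natively rather than by an external simulator.
`random_tree()` builds a topology by sequential random coalescence of
lineage pairs — the simplest exchangeable law; nothing downstream
depends on the topology distribution — and draws each branch length
independently from an exponential with configurable mean (default 0.1
substitutions/site, a moderately diverged alignment).
`simulate_alignment()` draws each column's root state from the model's
equilibrium and propagates states down the tree from the rows of
$P(t)$.  The simulator's correctness is anchored by distributional
checks in the suite: branch-length means, leaf residue frequencies
against $\pi$, and two-leaf joint frequencies against
$\pi_a P(t_1+t_2)_{ab}$, each within three standard errors at $10^4$
draws.

What the simulator does *not* emulate: indels (columns are ungapped
unless profiles are constructed by hand), among-site rate multipliers
beyond what column-specific matrices express, non-stationary root
distributions, and alignment error.  Passing tests therefore demonstrate
correctness of the likelihood, gradients and optimizer under the model's
own assumptions, not robustness of inference on real alignments.

## Numerical choices and problem sizes

* Transition-matrix entries in $(-10^{-10}, 0)$ from round-off are
  clipped to 0 without renormalizing rows (preserving row sums to first
  order); entries below $-10^{-8}$ raise an error, since they indicate a
  genuinely failed decomposition.
* A rate matrix whose spectrum contains an eigenvalue above $10^{-8}$ is
  rejected as not a proper generator.
* Gradient verification uses central finite differences with the mixed
  comparison $|a-f|/\max(|f|,1)$: large components are checked
  relatively, near-zero ones absolutely, because a central difference of
  a log likelihood carries round-off of order
  $\varepsilon\,|L|/\mathrm{step}$ and a purely relative comparison of a
  tiny component measures the oracle rather than the gradient.  For
  20-state instances the oracle uses step $10^{-5}$, near the cube-root
  optimum of the truncation/round-off trade-off.
* Parallelism (`threads`) distributes fixed-size column chunks (512
  columns) over forked workers and reduces them in deterministic order;
  the chunking is independent of the thread count, so results are
  bitwise identical for any `threads` value.
* The suite's problem sizes — trees of 2–128 leaves, 1–2000 columns,
  parameter-recovery runs at 64 taxa × 2000 columns over 10 seeds —
  were chosen as the smallest instances at which every property is
  meaningfully exercised.

## Design decisions that were genuinely open

* **Stopping rule.** "Improvement below 0.0001 %" is interpreted as
  relative improvement of $|L|$ between successive outer L-BFGS rounds.
* **Free-parameter count.** The $-1$ in the count is realized by mean-
  rate normalization rather than by fixing one exchangeability; both
  conventions appear in the field (the fixed-coordinate one is what a
  PAML-style file with a reference exchangeability of 1 encodes) and
  they parametrize the same model manifold.
* **Initialization.** Fits default to equal exchangeabilities and
  uniform equilibrium; an explicit `init` (e.g. an empirical
  amino-acid matrix) can be supplied.
* **Gap handling and root prior** are as described above; neither is
  forced by the likelihood theory, both follow dominant practice.
* **IQ-TREE/RAxML parametrization.** Tools in that family write
  $Q = R\,\mathrm{diag}(\pi)$ with symmetric $R$.  That maps to this
  package's parametrization by $s_{ij} = r_{ij}\sqrt{\pi_i \pi_j}$ (up
  to overall scale); the conversion is documented rather than supported
  as a second first-class parametrization.

## Known limitations

* Only real spectra are supported, i.e. time-reversible models; the
  adjoint formula itself would apply to any diagonalizable generator,
  but non-reversible (complex-eigenvalue) generators are out of scope.
* Per-column equilibria fitted by maximum likelihood are noisy: at 64
  taxa a column's $\hat\pi$ scatters around the truth with
  multinomial-scale error (mean total-variation distance to the shared
  truth $\approx 0.14$ in the suite's shared-S recovery check), and
  unrelated columns' estimates can differ by TVD $0.3$–$0.5$.  This is
  inherent to per-column estimation at realistic depths — exactly the
  overfitting that motivates regularization or low-dimensional
  embeddings of $\pi$ — not an artefact of the optimizer; the suite
  asserts the scatter is centred on the truth rather than pretending it
  is absent.
* There is no tree-topology search and no built-in branch-length
  optimization loop; branch-length *gradients* are produced by every
  reverse pass, and tests exercise an optimizer over them, but the
  product surface fits rate-matrix parameters on a fixed tree.
* Among-site rate-category mixtures (Gamma rates, C10–C60-style mixture
  weights) are expressible only implicitly via column-specific models;
  no mixture-weight machinery is provided.

## A worked example

```{r example}
tree <- random_tree(16, branch_length_mean = 0.12, seed = 7)
truth <- random_reversible_params(4, seed = 8)
sim <- simulate_alignment(tree, column_models(truth), seed = 9,
                          n_columns = 400)
patterns <- compress_columns(sim$profiles)

bundle <- loglik_and_grad(tree, patterns$profiles, column_models(truth),
                          weights = patterns$weights)
bundle$loglik

fit <- fit_model(tree, patterns$profiles, "global_gtr",
                 weights = patterns$weights)
fit
cor(fit$params[[1]]$exch / sum(fit$params[[1]]$exch),
    truth$exch / sum(truth$exch))
```
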