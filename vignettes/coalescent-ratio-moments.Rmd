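---
title: "Moments and ratio approximations for coalescent tree summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moments and ratio approximations for coalescent tree summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalratios)
```

## The model

We work under the standard Kingman coalescent for a haploid population of
constant size $N$: a genealogy of $n$ sampled lineages is generated
backwards in time, and while $k$ lineages are active the waiting time
$T_k$ to the next coalescence is exponential with rate $\binom{k}{2}$,
with the merging pair uniform over the $\binom{k}{2}$ unordered pairs.
Time is measured in units of $N$ generations, so
$E[T_k] = 2/(k(k-1))$ and $\mathrm{Var}[T_k] = 4/(k^2(k-1)^2)$.

Six summaries of the resulting random tree are covered: the height
$H_n = \sum_{k=2}^n T_k$, the total branch length
$L_n = \sum_{k=2}^n k\,T_k$, the total external branch length $E_n$
(each leaf's branch up to its first coalescence), the total internal
branch length $I_n = L_n - E_n$, the mean basal branch length $B_n$
(the two branches incident to the root), and the $T_k$ themselves.
$H_n$, $L_n$, $E_n$ exist for $n \ge 2$, $I_n$ for $n \ge 3$, and $B_n$
for $n \ge 4$; the package enforces these domains and distinguishes
*undefined* (outside the domain) from *divergent* (a limit growing
without bound) — callers must never confuse the two.

All first and second moments of these summaries, and the covariances of
all fifteen pairs, are polynomial expressions in $n$ and the harmonic
sums $S_{p,m} = \sum_{k=1}^m k^{-p}$ ($p = 1, 2, 3$). Thirteen of the
fifteen covariances are exact; those of $(E_n, B_n)$ and $(I_n, B_n)$
are themselves approximations, and every quantity that consumes them
carries an `approximate` flag.

## Delta-method ratio approximations

For a ratio $X/Y$ of two summaries, the package uses the Taylor
(delta-method) expansions around the mean vector:
$$\tilde E[X/Y] = \frac{E[X]}{E[Y]} - \frac{\mathrm{Cov}[X,Y]}{E[Y]^2}
  + \frac{E[X]\mathrm{Var}[Y]}{E[Y]^3} \quad\text{(second order)},$$
$$\widetilde{\mathrm{Var}}[X/Y] = \Bigl(\frac{E[X]}{E[Y]}\Bigr)^2
  \Bigl(\frac{\mathrm{Var}[X]}{E[X]^2}
  - \frac{2\,\mathrm{Cov}[X,Y]}{E[X]E[Y]}
  + \frac{\mathrm{Var}[Y]}{E[Y]^2}\Bigr) \quad\text{(first order)}.$$

Two independent implementations exist for every canonical pair: the
*generic composition* (`ratio_mean_approx()`, `ratio_var_approx()`),
which feeds the exact moments and covariances through the formulas
above, and a *transcribed closed form* (`ratio_mean_closed()`,
`ratio_var_closed()`). The published renderings of the closed forms are
long and typographically fragile (flattened fraction bars make
$S_{2,n-1}$, $S_{2,n}\cdot n$, and $S_{2,n} - 1$ easy to confuse), so
each transcription was reconstructed against three oracles before being
frozen into the package: algebraic identities (e.g.
$\mathrm{Var}[H_n] = \sum_k \mathrm{Var}[T_k]$ by independence of the
coalescence times), Monte-Carlo estimates, and the printed limit
constants. The test suite then requires the two paths to agree *as
exact rationals* for every pair and every valid $n \le 200$ (and across
$k$ for pairs with $T_k$) — an equality test with no tolerance at all,
which is the reason the package does exact arithmetic in the first
place. The generic composition is the runtime path; the closed forms
exist as the cross-check.

Reciprocal orientations ($H/E$ instead of the canonical $E/H$) run
through the same generic machinery by swapping numerator and
denominator; only canonical orientations carry transcribed closed forms
and exact limits. Where a required mean vanishes ($I_2$ has expectation
0) or a summary is undefined ($B_n$ for $n < 4$), the functions fail
loudly rather than returning a limit or a placeholder.

## Exact arithmetic and the limit basis

Finite-$n$ values are exact rationals (`rational()`), implemented on
arbitrary-precision integer arithmetic in compiled code and always kept
in canonical lowest-terms form so that equality is decidable. Doubles
are produced only at rendering time (`as.numeric()`), by default shown
at 5 decimal places to match the precision at which the constants are
conventionally printed.

Every finite $n \to \infty$ limit in the compendium lies in the rational
span of $\{1, \pi^2, \pi^4, \pi^6, \zeta(3), \pi^2\zeta(3)\}$
(`zeta_combo()`), since $\zeta(2), \zeta(4), \zeta(6)$ are rational
multiples of powers of $\pi$. Limits are stored as exact coefficient
vectors over this basis, obtained by taking the symbolic limit of the
finite-$n$ composition, and are verified in the tests in two independent
ways: against the printed 5-decimal constants, and against the finite-$n$
formulas evaluated numerically at $n = 10^7$. One published limit
rendering was recovered this way: the limiting variance approximation
for $B_n/E_n$ is $-\pi^4/36 + \pi^2/4 + 1/2 \approx 0.26159$ (the
flattened rendering could be misread as $-\pi^4/30$, which is
numerically inconsistent with the printed decimal).

For very large $n$, exact harmonic sums are computationally meaningless
(the denominator of $S_{1,n}$ grows like $e^n$), so every formula also
has a double-precision path (`exact = FALSE`) with harmonic sums
computed through the polygamma function:
$S_{1,n} = \psi(n+1) + \gamma$, $S_{2,n} = \pi^2/6 - \psi'(n+1)$,
$S_{3,n} = \zeta(3) + \psi''(n+1)/2$. This path is what the tests use to
confirm convergence of finite-$n$ values to the exact limits. Entries
whose convergence is logarithmic (anything with $S_{1,n-1}$ surviving in
a denominator, e.g. $\tilde E[H_n/L_n] \to 0$ or
$\tilde E[L_n/I_n] \to 1$) are still ~0.06 away from their limits at
$n = 10^7$; for those the tests assert monotone approach rather than
5-decimal agreement, which no affordable $n$ could deliver.

## The simulator

The validation simulator draws genealogies exactly as the model above
prescribes. Design choices:

* **Counter-based randomness.** Replicate $r$ of a run with seed $s$
  uses its own SplitMix64 stream derived from $(s, r)$, so a replicate
  can be regenerated in isolation and chunked runs give bit-identical
  results. All stochastic outputs record seed and replicate count.
* **Topology-based $B_n$.** The basal summary is measured on the
  simulated topology as the mean of the two root-incident branch
  lengths. The tidy representation $B_n = \sum_k T_k/(k-1)$ holds only
  in distributionally aggregated form, *not* per realization: at
  $n = 4$ the topology-based variance is $335/324$ (matching the exact
  formula) while the variance of the linear combination is $334/324$.
  The simulator therefore never uses the linear-combination shortcut,
  and the agreement of its moments with the exact formulas is itself a
  test. $B$ is reported as `NA` for $n < 4$ unless explicitly requested
  (`basal_always = TRUE`).
* **Per-tree identities** ($I = L - E$, $H = \sum T_k$,
  $L = \sum k T_k$, two root children) are asserted on simulated trees
  to $10^{-12}$.
* **Newick interchange** (`write_newick()`) uses unquoted integer leaf
  labels and up to 12 significant digits; round-trips through standard
  tree tooling preserve $L$ and ultrametricity.

What the simulator emulates is exactly the null model the formulas
describe — constant population size, no mutation, recombination,
migration, or selection. Passing Monte-Carlo checks therefore validate
the algebra, not the biological adequacy of the model; with real data,
departures from these assumptions (growth, structure, selection) move
every one of these summaries.

## Tolerances and problem sizes

* Monte-Carlo recovery uses $10^5$ replicates at $n \in \{5, 10, 20\}$
  and asserts agreement within 4 standard errors for all exact means,
  variances, and covariances. With roughly 340 such assertions under a
  fixed seed, the expected number of false alarms is far below one.
* The $(E_n, B_n)$ and $(I_n, B_n)$ covariance formulas are
  approximations whose error the theory does not quantify. Measured at
  $10^6$ replicates, the systematic gap is $+0.026/+0.033/+0.019$
  (coalescent units$^2$) at $n = 5/10/20$ for $(E, B)$, mirrored with
  opposite sign for $(I, B)$ since their sum, $\mathrm{Cov}[L, B]$, is
  exact. The documented test tolerance for these two entries is
  therefore 4 SE plus an absolute allowance of 0.05.
* Expectation approximations for ratios are accurate: at $n = 50$ with
  $10^5$ replicates the relative deviation from simulation is under 5%
  for all pairs among $\{H, L, E, I\}$ (observed ~1%). Variance
  approximations are noticeably rougher at small $n$ — for these, the
  tests assert only that approximation and simulation agree in their
  trend as $n$ grows. Users needing precise ratio variances at small
  $n$ should simulate instead.
* The exact-equivalence sweep runs to $n = 200$ and $k \le n$ at
  $n \in \{5, 10, 20\}$; the rationals involved reach a few hundred
  digits, which the arithmetic backend handles in well under a minute.

## Limitations

Higher-order Taylor corrections, exact distributions of ratios, moments
under demographic change, and third and higher moments are out of scope.
The limits of reciprocals with divergent denominators (e.g. $T_k/L_n$)
are not tabulated; compute finite-$n$ values instead. For other harmonic
orders than $p \in \{2, 3, 4, 6\}$, `harmonic_limit()` returns a
numerical $\zeta(p)$ rather than an exact basis element.
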