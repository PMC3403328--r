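---
title: "State reduction and minimax control of probabilistic Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State reduction and minimax control of probabilistic Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbnred)
```

## The model

A Boolean network (BN) over genes $v_1, \dots, v_n \in \{0,1\}$ updates all
genes synchronously: $v_i(t+1) = f_i(v_{i_1}, \dots, v_{i_k})$, where the
$v_{i_j}$ are the parents of gene $i$ and $k \le K$, the maximum in-degree.
A probabilistic Boolean network (PBN) gives each gene a set of candidate
predictors with selection probabilities $c_j^{(i)}$ summing to one. With
independent selection per gene, the network is equivalently a finite
collection of constituent BNs — one predictor per gene, all combinations —
where constituent $j$ is selected each step with probability
$q_j = \prod_i c_{j_i}^{(i)}$. `pbnred` supports both forms (`pbn()` and
`pbn_explicit()`) and compiles the former into the latter with
`as_constituents()`.

States are encoded decimally, $z = 1 + \sum_i 2^{n-i} v_i \in
\{1,\dots,2^n\}$, with the **first gene as the most significant bit**; the
same convention orders truth-table rows (first listed parent most
significant) and control values $u = 1 + \sum_i 2^{m-i} v_{n+i}$. The
convention is arbitrary but frozen, so that matrix indices, truth tables
and state labels all address each other consistently. All public
interfaces are 1-based.

The dynamics are summarised by column-stochastic transition matrices
$A(u)$, one per joint value $u$ of the $m$ control nodes:
$A(u)_{ij} = \sum_{k \in I(j \to i, u)} q_k$, the total selection
probability of the constituents that map state $j$ to state $i$ under the
control bits of $u$. `build_transition_matrix()` assembles these sparsely
(each column holds at most $N$ nonzeros).

**Perturbation.** Independently of the Boolean update, each gene may flip
with probability $p$ per step. With probability $(1-p)^n$ no gene flips
and the BN update applies; otherwise the state jumps according to the
off-diagonal part of the Kronecker power of the single-gene kernel
$Q = \begin{pmatrix}1-p & p\\ p & 1-p\end{pmatrix}$:
$$\tilde A = (1-p)^n A + P, \qquad P = Q^{\otimes n} - (1-p)^n I.$$
$P$ is symmetric with zero diagonal, entry $p^h (1-p)^{n-h}$ between
states at Hamming distance $h \ge 1$, and every row and column sum equal
to $\xi = 1-(1-p)^n$. The implementation materialises $P$ densely for
$n \le 12$ directly from the Hamming-distance formula — algebraically
identical to the iterated Kronecker product, but with a hard zero
diagonal and no accumulated rounding, so the row-sum identity holds to
machine precision. Gene 1 is the outermost Kronecker factor, matching the
state encoding. One $p$ applies to all genes, and the same $P$ is added to
every $A(u)$: perturbation acts on the internal state only, and nothing in
the model makes the flip mechanism depend on the applied control.

## State reduction

Transient states that the network can never (or almost never) enter
contribute nothing to long-run behaviour or to worst-case control, but
they dominate the size of the state space. `reduce_network()` deletes
them by a transition-probability criterion:

* the working matrix is $\tilde A(u)$ when $p > 0$, else $A(u)$;
* a state $i$ is **deletable** when, for *every* control value $u$, its
  truncated inflow $\sum_{j \in \text{kept}} M(u)_{ij}$ is at or below
  the threshold $\xi = 1 - (1-p)^n$;
* deletion proceeds in rounds: all currently deletable states are removed
  together, the corresponding rows and columns are dropped, and inflows
  are recomputed, until no state qualifies. The threshold stays fixed
  while the truncated sums shrink;
* **critical states** — the attractors plus the initial state $z_0$ — are
  never deleted.

Design choices worth making explicit, since several are genuinely open:

* *Threshold semantics.* The comparison is non-strict ($\le \xi$). With
  $p = 0$ the threshold is $\xi = 0$ and the rule reduces to the exact
  zero-inflow test: a state is deleted only if the surviving network can
  never enter it. With $p > 0$, $\xi$ equals the row sum of $P$, so a
  state whose entire inflow is perturbation mass is deletable.
* *Every-control quantification.* A state is only deleted if it is
  (near-)unreachable under **all** controls. Quantifying over any single
  control would let some other control steer the network into a deleted
  state, and the equivalence of the reduced control problem (below) would
  fail.
* *Batch deletion.* Removing all simultaneously-deletable states per
  round makes the result deterministic and order-independent. A
  `order = "sequential"` mode (one state at a time, ascending index) is
  available for comparison; on the unperturbed zero-inflow criterion both
  reach the same fixpoint.
* *Attractors as bottom SCCs.* For the preserved set, attractor states
  are defined as the states lying in bottom (terminal) strongly connected
  components of the support digraph of $A(u)$, unioned over controls
  (computed via igraph). For a deterministic BN this is the classical
  attractor set; for a PBN it is the recurrent state set of the support
  chain.
* *Termination.* Iteration runs to the no-deletable-state fixpoint. One
  might hope to continue "until only critical states remain", but for
  general models that is unattainable (a transient state with persistent
  inflow from kept states is not deletable and not critical), so the
  fixpoint is the semantics.

**A structural property of the threshold rule.** For ensembles with
equiprobable constituents ($q_j = 1/N$), every nonzero entry of $A$ is at
least $1/N$, so any state with at least one surviving unperturbed
predecessor has truncated inflow at least $(1-p)^n/N$ plus perturbation
mass. Whenever $(1-p)^n/N > \xi$ — which holds for all $N \le 8$ and
$p \le 0.01$ at $n \le 12$ — no such state can ever fall at or below the
threshold, and the available slack from already-deleted perturbation mass
(at most $\xi$) cannot bridge the gap. The deletion rule then provably
coincides with the $p = 0$ zero-inflow rule, and the reduction rate is
**independent of $p$** across that regime. Reduction rates that rise
steeply with $p$ therefore require either very unequal selection
probabilities (some $q_j \lesssim \xi$) or a different deletion
criterion; under this package's generator (equiprobable constituents,
below) they cannot occur, and the acceptance checks of the
perturbation-rate study reflect that: the monotone trend holds (with
equality), while the specific large spread between rates at
$p = 10^{-3}$ and $p = 10^{-2}$ is not reproduced. Measured under the
generator defaults, the mean rate at $n=6$, $N=4$, $K=2$ is ~45–52 %
(seed-dependent) and identical at every $p$ in $[10^{-3}, 10^{-2}]$ on
matched seeds.

## Minimax control

Given a terminal cost $C$ on states (default $C(z) = z$, i.e. higher
state labels are the undesirable phenotypes), horizon $M$, and initial
state $z_0$, the worst-case-optimal feedback value is
$$J_M(z) = C(z), \qquad
  J_t(z) = \min_{u} \max_{z' \in F(z,u)} J_{t+1}(z'),$$
with $F(z,u)$ the support of column $z$ of the **unperturbed** $A(u)$.
Using $\tilde A$'s support instead would be degenerate: under perturbation
every state reaches every state, so the worst case would always be
$\max_z C(z)$ regardless of control. Perturbation thus enters the control
problem through the reduction threshold, not through the adversary's move
set. The worst case is taken with respect to the reachable set — the
adversary may pick any successor with positive probability — which is the
natural robust reading of "minimise the maximum cost"; accordingly the
value update uses a max over successors, as the min–max objective
requires. Ties in the minimising control go to the smallest control
index, and successors are scanned in ascending state order, so results
are bit-reproducible across platforms.

On a reduced state set $R$, the same recursion runs on the restricted
matrices with costs still indexed by original state labels; the solver
first verifies $F(z,u) \subseteq R$ for all $z \in R$ and raises a
`reduced-model-inconsistency` error otherwise. When that guard holds,
deleted states are unreachable from $R$, so trajectories, costs, and
hence the DP values on the original and reduced networks coincide —
`compare_original_reduced()` computes both and reports the equality,
and the test suite asserts it across a grid of random instances
($n{-}m = 4,5$ internal genes, $m \in \{1,2\}$, $N \in \{2,4,8\}$,
$K \in \{2,3\}$, $p \in \{0, 0.01\}$, $M = 20$, 120 instances).

**Oracles.** Two independent solvers guard the DP: `game_tree_value()`, a
memoisation-free recursion over the game tree (exact equality required),
and `open_loop_bruteforce()`, which enumerates all $2^{mM}$ fixed control
sequences and propagates reachable sets (feedback dominates open loop;
equality for deterministic single-constituent networks, where observing
the trajectory carries no information). Both guard their instance size
and are used in the tests at $n \le 4$, $m \le 2$, $M \le 4$.

**Switch-budget mode.** `minimax_dp(..., switch_budget = H)` restricts
the controller to at most $H$ changes of control value over the horizon
(the first choice is free), via a DP over (state, remaining switches,
previous control). This is one consistent completion of a
budget-indexed value table $J(z_t, h_t)$ whose recursive semantics are
otherwise underdetermined; it is off by default, and $H \ge M-1$
reproduces the unconstrained solution exactly ($H = 0$ equals the best
constant-control policy, which the tests verify against direct set
propagation).

## The in-degree-one ensemble

With $K = 1$ and constants excluded, each gene's predictor is one of $2n$
literals (copy or negate one gene), giving $(2n)^n$ networks.
`image_distribution()` builds every network's deterministic state map by
exhaustive enumeration (guarded to $n \le 6$) and tabulates the number of
states with at least one predecessor — the nonzero rows of the transition
matrix. The image size always equals $2^d$ where $d$ is the number of
distinct genes used as parents (asserted during enumeration). Two closed
forms are verified against the enumeration: networks with full image
number $n!\,2^n$ (choose an arrangement of $n$ distinct parents, then
polarities), and their proportion $n!/n^n \to 0$, strictly decreasing.
The general closed-form expression for the count at $2^{n-k}$ nonzero
rows involves a nested multinomial whose index semantics are ambiguous as
usually printed; the brute-force enumeration is treated as normative and
only the $k = 0$ term is asserted in closed form. Constants are excluded
here because the $(2n)^n$ census counts parent-polarity choices only; the
random generator for $K \ge 2$ (below) draws truth tables uniformly and
therefore can produce constants.

## The random-PBN generator

`generate_random_pbn(n, m, N, K, p, seed)` defines the study conditions
for all ensemble experiments and is itself part of the tested surface:

* $N$ constituent BNs with **equiprobable** selection, $q_j = 1/N$;
* per gene and constituent, in-degree uniform on $1..K$ ($K$ is a
  maximum, not an exact in-degree), distinct parents uniform over all
  $n+m$ nodes, truth table uniform over all $2^{2^k}$ tables;
* identical seeds give bit-identical networks, matrices, reductions and
  DP values; experiment runners derive and report one seed per replicate
  so any row of a report can be replayed in isolation.

Defaults ($n = 6$, $N = 4$, $K = 2$, 10 replicates, $M = 20$,
$C(z) = z$, controlled runs with $n - m$ internal genes) mirror the
standard small-ensemble design for this class of models. The uniform
choices are maximum-entropy defaults: real regulatory networks are
sparser, enriched for canalising functions, and have highly non-uniform
selection probabilities, so passing ensemble tests demonstrates
correctness of the machinery on exchangeable random instances, not
biological realism. In particular (see the structural property above),
equiprobable constituents pin the reduction rate to its $p = 0$ value;
ensembles intended to show $p$-sensitive reduction would need unequal
$q_j$ spanning below $\xi$.

## Numerical choices and problem sizes

* Support/zero tolerance $10^{-12}$ (selection-probability products of
  realistic depth cannot underflow this); column-stochasticity asserted
  at $10^{-9}$ on construction; the perturbation row-sum identity is
  tested at $10^{-12}$.
* $A(u)$ sparse (`dgCMatrix`); $\tilde A$ and $P$ dense, limited to
  $n \le 12$ (a $4096^2$ dense matrix, 134 MB).
* Degenerate inputs: empty reachable sets are impossible for
  column-stochastic matrices and raise an internal-consistency error if
  ever observed; `m = 0` is a single control value $u = 1$; an
  already-reduced model yields zero further deletions (fixpoint).
* Test problem sizes were chosen to keep the whole suite in the
  few-minute range while exercising every code path: exhaustive encoding
  checks to $n = 12$, enumeration to $n = 5$, oracle cross-checks at
  $n \le 4$, ensemble studies at $n = 6$ with 10 replicates.

## Known limitations

* The reduction preserves worst-case control exactly only when the
  reachable-set guard holds; with $p > 0$ and very unequal $q_j$ the
  threshold can delete states that remain reachable, in which case the
  solver refuses the reduced model rather than silently computing a
  different value.
* Steady-state-distribution preservation under deletion is only
  exercised empirically at $p = 0$ and small $n$, not proved.
* Asynchronous update semantics, gene-specific perturbation
  probabilities, expected-cost (average) and infinite-horizon control,
  and inference of PBNs from expression data are out of scope.
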