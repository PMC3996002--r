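---
title: "Four-Russians accelerated Nussinov folding: methods and design"
author: "FourRussiansRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-Russians accelerated Nussinov folding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FourRussiansRNA)
```

## The model

The basic RNA folding problem asks for a secondary structure that maximizes
the number of complementary base pairs (A–U, C–G) under two constraints:
each position pairs at most once, and no two pairs cross — for pairs
$(i,j)$ and $(k,l)$ with $i<k$, either $i<k<l<j$ (nested) or $i<j<k<l$
(disjoint). This ignores stacking energies and loop entropies; it is the
combinatorial core on which energy-based folders build, and the non-crossing
condition is exactly what makes dynamic programming over subsequences work.

Let $D(i,j)$ be the optimal pair count for the subsequence $i..j$, with
$D(i,i-1)=D(i,i)=0$. For $i<j$:

$$D(i,j)=\max\Big\{\, b(S_i,S_j)+D(i+1,j-1),\ \max_{i+1\le k\le j}
D(i,k-1)+D(k,j) \Big\}$$

where $b(\cdot,\cdot)$ is 1 for complementary bases and 0 otherwise. The
answer is $D(1,n)$; recording the argmax of each cell (the table $D^*$)
makes traceback a mechanical replay. The split maximum over $k$ costs
$\Theta(n)$ per cell, giving $O(n^3)$ total. Note that $k=i+1$ contributes
$D(i,i)+D(i+1,j)$, so "leave $i$ unpaired" is already expressible by the
split case and the recurrence needs no third branch.

All engines in this package compute this same table, cell for cell; the
test suite and `selfCheck()` enforce exact (not approximate) table
equality across all six engines.

## Why difference vectors work

Adjacent cells differ by at most one: going right along a row the table is
non-decreasing with steps in $\{0,1\}$, and going down a column it is
non-increasing with steps in $\{0,-1\}$ (removing one position from a
subsequence destroys at most one pair). Hence $q$ consecutive row cells are
represented exactly by their first value plus a $q$-bit *horizontal
difference vector* $v$ (running totals $V$), and $q$ column cells by an
initial value plus a *vertical difference vector* $\bar v$ (running totals
$\bar V$). The split maximum over one aligned group of $q$ cells collapses
to

$$D(i,l)+D(l+1,j)+\max_{0\le k<q}\big(V_k+\bar V_k\big),$$

and the inner maximum depends only on the two bit codes. Precomputing it
for all $2^q\times 2^q$ code pairs (table $R$, with the argmax for
traceback) turns $q$ split terms into one constant-time lookup — the
Four-Russians device. With $q\approx\log n$ the total drops to
$O(n^3/\log n)$; empirically the counters reported in `opStats()` show the
split-work identity: residual evaluations plus $q\times$ lookups exactly
equals the plain engine's $n(n-1)(n+1)/6$ split terms.

### Grouping conventions

The split combines column $k-1$ with row $k$, so column groups are aligned
at $kq..(k+1)q-1$ and row groups at $kq+1..(k+1)q$ — offset by one. With
this global alignment the $g$-th column group of row $i$ always meets the
$g$-th row group of column $j$, group vectors are shared by every cell that
uses them, and each is encoded exactly once, when its last cell is filled.
Cells of a row not covered by full groups (at most $2q$: up to $q-1$ before
the first full group, up to $q$ after the last) are evaluated by the plain
recurrence; the engines assert the unit-step invariants whenever they
encode a group, so a corrupted table fails fast rather than silently.

Bit $p$ of a code carries the step at group offset $p$; bit 0 is
structurally zero because $V_0=0$ by definition, so only $2^{q-1}$ of the
$2^q$ codes are reachable. $R$ is nevertheless allocated over all
$2^q\times 2^q$ pairs — a deliberate 4-fold redundancy that buys flat,
branch-free indexing — and the decoder ignores bit 0, so even unreachable
entries agree with the direct-scan oracle `groupCombinationOracle()`.

### The q = 1 boundary

With $q=1$ every group is a single cell and the method degenerates to plain
Nussinov routed through (trivial, all-zero) lookups. Two boundary groups
exist only as base cases — the column group covering column 1 and, for each
column $j$, the single-row group $\{j\}$ whose value is $D(j,j)=0$ — and
are registered explicitly before the fill loops reach them.

## The engine family

All variants share the grouped DP and differ only in the preprocessing
schedule:

* **two-vector** (`twoVectorFold`): exhaustive $R$ built before any cell is
  filled. Fastest in practice once $n$ is large enough that most code pairs
  occur; the literature's empirical optimum is around $q=8$–$9$, and the
  package default is a conservative $q=4$.
* **FG** (`fgFold`): preprocessing interleaved with the fill. When a row
  group completes, its realized horizontal vector is expanded against all
  $2^q$ vertical codes and tabled per (row, group) with the group's initial
  cell $D(i,gq)$ folded in — so the same horizontal vector is re-expanded
  every time it recurs, which is exactly why FG is slower than two-vector.
  The table is indexed by (row, group, vertical code); a query adds the
  matched column group's initial value $D(gq+1,j)$. (The original
  formulation packs vectors in a base-$b$ encoding; this implementation
  reuses the binary codec shared by all engines, which changes constants
  only.)
* **partial memo** (`partialMemoFold`): like FG keyed on completion events,
  like two-vector keyed on vector pairs: a *new* horizontal code triggers
  expansion against all $2^q$ vertical codes, once ever. Memo size is
  exactly (distinct horizontal codes) $\times 2^q$.
* **full memo** (`fullMemoFold`): each (h, v) pair computed at first query.
  Memo size equals the number of distinct pairs queried, bounded by both
  $2^{2q}$ and the lookup count.

Memo tables live and die with one fold invocation; there is no
cross-sequence persistence, so counters are reproducible and there is no
hidden global state.

An accounting convention: a row group $(i,g)$ counts as *completed* (and,
for FG, is eagerly expanded) when all $q$ of its columns exist
($(g+1)q-1\le n$) and the group is queryable from row $i$ ($i\le gq$).
Groups whose last column is the final column of the table can never be
queried (the matching row group would exceed $n$) and are not expanded.

## The tiled wavefront engine

The parallel formulation fills the table by anti-diagonals. `tiledFold`
realizes its testable core without any GPU machinery: the padded table is
cut into $q\times q$ tiles (tile $(t_r,t_c)$ holds rows $t_rq+1..(t_r+1)q$
and columns $t_cq..(t_c+1)q-1$, inheriting the offset grouping), and tiles
with equal $t_c-t_r$ form one wavefront diagonal. The sequence is padded to
$n'=n+q-(n\bmod q)$ with the sentinel `N`, which pairs with nothing, so
every tile is full and $D(1,n)$ is unchanged; note the formula adds a full
extra tile when $q$ already divides $n$, which keeps the answer column
$n<n'$ strictly inside the tiled region. The number of tile diagonals is
taken as $n'/q$, the number of tile columns.

A tile consumes three kinds of data only:

1. stored difference vectors (with initial values) of tiles on strictly
   earlier diagonals — full-group lookups, plus two single-cell
   reconstructions for the paired-ends case at tile borders (one is the
   stored vertical initial value, the other the horizontal initial value
   plus the popcount of its code, i.e. the last running total);
2. locally recomputed diagonal blocks: the values of a diagonal tile
   $(a,a)$ depend only on sequence positions $aq+1..(a+1)q$, so each
   off-diagonal tile re-solves its own row block, its column block and (for
   diagonal distance 2) the block between them by plain Nussinov instead of
   reading neighbours' cells — duplicated work that mirrors the
   `init_diag` duplication of the parallel design and is included in the
   reported operation counts;
3. its own cells, filled column-by-column, bottom-up.

Because of (1)–(3), tiles within a diagonal are order-independent: the
engine processes them in a seed-shuffled serial order and the table is
bit-identical for every seed. "Parallelism" is thus a verified independence
contract rather than a threading implementation — the part of the design
that is testable on any platform. A dynamic guard counts every vector read
whose producing tile is not on a strictly earlier, already-stored diagonal
(`opStats(x)$guardViolations`); it is zero on every correct schedule, and
the traceback works unchanged because tiles record absolute split indices.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 4 | group/tile width (cells per lookup), integers 1–12; memory for $R$ is $O(4^q)$, so 12 is a hard guard |
| `minLoop` | 0 | minimum unpaired bases between the ends of a pair; 0 reproduces the bare recurrence (adjacent bases may pair), 3 is the common biological hairpin constraint |
| `wobble` | off | adds G–U to the pairing predicate; the default rule is strict A–U/C–G |
| `shuffleSeed` | none | within-diagonal tile order for `tiledFold`; any seed yields the identical table |

Tie-breaking is fixed everywhere so that tracebacks are deterministic:
pairing the two ends wins over an equal-valued split, and among equal
splits the smallest absolute $k$ wins (the $R$ table stores the smallest
argmax within a group, and groups are scanned in ascending position).
Optimal structures are generally not unique; engines therefore guarantee an
*optimal, valid* witness, not a particular one, and tests validate
witnesses structurally (pair count, complementarity, non-crossing) rather
than comparing them across engines.

## Synthetic data, and what the tests do and do not show

The generator `randomRnaSequence(n, seed)` draws bases i.i.d. uniform over
{A, C, G, U} — the "random strings" regime used for correctness and
work-count experiments. It restores the caller's RNG state, so fixed
`(n, seed)` pairs are reproducible fixtures everywhere (tests, self-check,
the acceptance script).

Uniform sequences are the right stress test for *algorithmic correctness*:
they exercise dense pairing possibilities, tie-heavy cells and all residual
shapes. They do not emulate real RNA — no GC skew, no local repeats or
hairpin bias, no conserved stems — and the pair-maximization objective
itself is not a thermodynamic model, so agreement on random strings says
nothing about biological accuracy of predicted structures. What the
passing suite does establish: all six engines compute identical tables
(hence any will do for downstream use), the tables equal an independent
exhaustive enumeration where that is feasible, and the instrumented work
counts realize the promised $1/q$ split-work reduction.

Problem sizes were chosen to make each property observable at desk scale:
exhaustive oracle comparison over all $4^n$ sequences up to $n=6$ (5,460
sequences), sampled comparison with witness validation at $n=7..12$, the
six-way agreement grid over $n\in\{16,50,100,257\}\times q\in\{2,3,4,8\}$
(50 seeded runs; 257 is deliberately not divisible by 8, and tiny $n<q$
runs cover the degenerate grouping), and the work-count identity at
$n=512$, $q=8$. Per-module unit tests repeat the same properties on
smaller grids.

## Known limitations

* Pure-R engines: asymptotics are realized in operation counts, not
  wall-clock; a compiled implementation would be needed for sequence
  lengths in the thousands.
* No energy model, partition function, suboptimal structures or
  pseudoknots; `maxPairs` is a combinatorial score, not a free energy.
* `q` beyond 10 is legal but the $4^q$-entry table build dominates long
  before the asymptotic benefit appears at realistic $n$.
* The brute-force oracle is capped at $n=16$ by design; above that only
  cross-engine identity (not independent enumeration) is available.
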