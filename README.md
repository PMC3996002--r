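# FourRussiansRNA

Maximum non-crossing complementary base-pair matching for RNA sequences —
the Nussinov dynamic program — together with a family of Four-Russians
accelerated engines that compute *cell-identical* tables while doing a
factor-q less split work, and a tiled diagonal-wavefront engine whose
tile-independence contract (the testable core of a GPU formulation) is
verified at run time.

The package is for people studying or teaching DP speedup techniques on a
real bioinformatics recurrence, and for anyone who needs a fully
instrumented, oracle-checked reference implementation of base-pair
maximization with traceback to standard structure formats.

## The model

For a sequence S of length n over {A, C, G, U}, D(i, j) is the maximum
number of non-crossing complementary pairs (A–U, C–G) in the subsequence
i..j, with D(i, i−1) = D(i, i) = 0 and, for i < j,

    D(i,j) = max{ b(S[i], S[j]) + D(i+1, j−1),
                  max_{i+1 ≤ k ≤ j} D(i, k−1) + D(k, j) }

where b is the 0/1 pairing predicate. The answer is D(1, n); replaying the
stored argmax decisions yields an optimal structure. The split maximum
makes the plain algorithm O(n³).

Because adjacent cells differ by at most 1, q consecutive cells are an
initial value plus a q-bit difference vector; the split maximum over an
aligned group collapses to one lookup in a table R precomputed over all
2^q × 2^q vector pairs — the Four-Russians speedup, O(n³/log n) at
q ≈ log n. Six engines share this machinery and differ only in the
preprocessing schedule:

| engine | preprocessing |
|---|---|
| `nussinovFold` | none (reference O(n³) DP) |
| `twoVectorFold` | exhaustive R before the DP starts |
| `fgFold` | interleaved, per (row, group), duplicated for repeated vectors |
| `partialMemoFold` | all 2^q partners of each *new* horizontal vector |
| `fullMemoFold` | each (h, v) pair at first query |
| `tiledFold` | exhaustive R + q×q tiles filled per wavefront diagonal |

## Worked example

```r
library(FourRussiansRNA)

seq <- rnaSequence("GGGAAAUCCCAGCUUCGGCUG", name = "demo")
fr  <- twoVectorFold(seq, q = 4)
fr
#> FoldResult [two-vector] 'demo': n = 21, q = 4, maxPairs = 8
#>   candidateEvaluations = 580, tableLookups = 240

st <- tracebackFold(fr)
dotBracket(st)
#> [1] ".(((..)))((((..()))))"
```

`maxPairs = 8` is the optimal pair count D(1, 21); the dot-bracket string
shows one optimal witness (balanced parentheses = paired positions, dots =
unpaired). `candidateEvaluations` counts split terms evaluated directly
(residual cells not covered by full groups) and `tableLookups` counts R
queries, each of which resolves q = 4 split terms at once.

The work-reduction identity is exact. At n = 512, q = 8:

```r
n512 <- randomRnaSequence(512, 1)
opStats(nussinovFold(n512))$candidateEvaluations
#> [1] 22369536            # = n(n-1)(n+1)/6 exactly
st <- opStats(twoVectorFold(n512, 8))
st$candidateEvaluations + 8 * st$tableLookups
#> [1] 22369536            # residuals + q x lookups = plain split count
```

Structures can also be written as connect tables (`writeCT`), sequences
read from FASTA (`readFoldFasta`), and everything driven from a shell via
the installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","rnafold-fr",package="FourRussiansRNA"))')" \
  fold --algorithm two-vector --q 8 input.fasta
```

`selfCheck()` runs the six-way agreement, oracle and R-table verification
suites and reports the first discrepancy with reproduction parameters.

## Documentation

The methods vignette (`vignettes/four-russians-folding.Rmd`) describes the
recurrence, the difference-vector encoding, the grouping and padding
conventions, the independence contract of the tiled engine, tie-breaking
rules, and what the synthetic-sequence tests do and do not establish.
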