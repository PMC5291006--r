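# lacunaseq

Fractal lacunarity analysis of mitochondrial DNA mutation load.

Resequencing a mitochondrial genome yields, per nucleotide position, a base
call that is either the reference base, a **homoplasmic** substitution (all
mtDNA copies mutated — a plain base), or a **heteroplasmic** call (a
fraction of copies mutated — encoded as a degenerate IUPAC symbol such as
`m` = a/c). Summarizing tens of scattered mutations of mixed type into one
comparable number is awkward with ordinary variant statistics. `lacunaseq`
treats mutations as disturbances of the sequence's fractal structure and
condenses them into a texture index:

1. **Weighted Chaos Game Representation (CGR).** Each length-*L* window of
   the subject sequence is addressed to a cell of a 2^L × 2^L matrix by
   recursive quadrant addressing (base layout `[[a, c], [g, t]]`). Windows
   containing degenerate symbols are expanded into all compatible pure
   strings, each contributing weight 1/(number of strings), so total matrix
   mass always equals the window count.
2. **Gliding-box lacunarity.** The matrix is min–max normalized, smoothly
   thresholded by the logistic sigmoid `J = 1 / (1 + exp(-k (I - σ)))`,
   and a b × b box glides over the image; with `Z_q` the q-th moment of
   the box mass over placements, `Λ(b) = Z₂ / Z₁² ≥ 1`.
3. **Hyperbola fit.** `L(b) = β b^(-α) + γ` is fitted to `Λ(b)` by
   bounded Levenberg–Marquardt least squares. **β is the per-subject
   biomarker**: a lower β corresponds to a higher degree of mutated
   frames.
4. **Cohort comparison.** One-tailed pooled-variance t-test on β between
   two groups, and a median-cutoff classifier (`β ≤ cutoff` ⇒ positive).

Defaults are the method's operating point: `L = 5` (32 × 32 image),
`k = 7`, `σ = 0.7`, boxes `b = 3 …` half the image side.

Intended users: bioinformaticians screening mtDNA resequencing cohorts
(aging/neurodegeneration studies), and anyone needing a validated
gray-scale gliding-box lacunarity engine with analytic test fixtures.

## Worked example

```r
library(lacunaseq)

# a synthetic 16.5 kb reference with human-mtDNA base composition,
# and an AD-scale call table: 14 homoplasmic + 3 heteroplasmic calls
reference <- randomSequence(16569, seed = 11, name = "mt-reference")
calls <- injectMutations(reference, nHomoplasmic = 14, nHeteroplasmic = 3,
                         seed = 12)
head(calls, 3)
#>    position ref_base call
#> 15      313        g    r
#> 7       546        t    a
#> 6      1500        g    a

res <- analyzeSubject(reference, calls, pipelineConfig(),
                      subjectId = "subj01", group = "AD")
res
#> SubjectResult 'subj01' (group AD): beta = 2.53888, alpha = 0.540727, gamma = 0.570306
#>   mutations: 14 homoplasmic, 3 heteroplasmic; L=5, b=3..16

res$fit
#> HyperbolaFit: L(b) = beta * b^-alpha + gamma
#>   alpha = 0.540727, beta = 2.53888, gamma = 0.570306
#>   RSS = 0.002307 over 14 points; converged: TRUE
round(rSquared(res$fit), 4)
#> [1] 0.9972
```

The call at position 313 is heteroplasmic (`r` = a/g, the mixture of the
reference `g` with a mutant `a`); the fit explains 99.7 % of the curve's
variance, and `beta = 2.54` is this subject's lacunarity index. For a
cohort, run `analyzeBatch()` over per-subject call tables, collect
`subjectTable()`, and feed it to `classifyByCutoff(tab, "median",
positiveGroup = "AD")` to get group means, the one-tailed t-test and the
confusion matrix of the median-β screen.

A command-line driver wrapping the same functions ships in
`inst/scripts/lacunaseq.R` (`run`, `cgr`, `lacunarity`, `fit`, `cohort`,
`simulate` subcommands); file formats are FASTA, 3-column TSV call tables,
dense CSV / ASCII-PGM images, `b,lambda` CSV curves and JSON fit reports.

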