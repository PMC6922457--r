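# tonalEntropy

Information-theoretic corpus analysis of the **melody** (highest-pitch) and
**bass** (lowest-pitch) lines of polyphonic keyboard music, for researchers
in computational music cognition and statistical learning.

From MusicXML scores (or a built-in synthetic corpus with known ground
truth) the package:

1. extracts one melody and one bass event sequence per piece — one event
   per onset, grace notes excluded, tie chains and equivalent simultaneous
   pitches counted once;
2. encodes them as **transposition-invariant interval patterns** (±1 per
   semitone relative to a window's first pitch, removing key effects) and
   estimates zeroth- to fifth-order Markov **transitional probability**
   (TP) distributions by plug-in maximum likelihood,
   P(e<sub>n+1</sub>|e<sub>n</sub>) = count(e<sub>n</sub>, e<sub>n+1</sub>) / count(e<sub>n</sub>);
3. derives **information content** I = log₂ 1/P bits per observed
   transition and **conditional entropy**
   H(B|A) = −Σᵢ Σⱼ P(aᵢ) P(bⱼ|aᵢ) log₂ P(bⱼ|aᵢ) bits per
   (aggregation unit, voice, order), pooling pieces within a unit by
   count-weighted averaging;
4. runs a **correlation-matrix PCA** over the transition-type × (unit,
   voice) profiles (eigenvalue > 1 adopted, loadings =
   eigenvector · √eigenvalue) and Pearson **entropy correlations** —
   melody vs bass per order, and major vs minor across tonic-paired keys —
   with two-sided p-values from t = r·√((n−2)/(1−r²)).

The synthetic generator (`syntheticCorpus()`) produces two-voice corpora
from interval Markov sources with a shared base, voice/unit perturbations
and a cross-voice-correlated "uncertainty" temperature, plus the analytic
entropies of every true source — so the entire pipeline is testable without
any external scores.

## Worked example

```r
library(tonalEntropy)

sc  <- syntheticCorpus(nUnits = 16, tonesPerVoice = 4000, alphabet = -6:6,
                       seed = 42)      # cross-voice uncertainty rho = 0.8
res <- runAnalysis(sc, template = "study1", orders = 0:2)
res
#> tonalEntropy analysis (study1, window convention, hash 91f3cc46)
#>   16 units, orders 0,1,2
#>   entropy cells: 96 (0 missing)
#>   order 0 PCA: PC1 85.75%, 2 components > 1
#>   order 1 PCA: PC1 85.75%, 2 components > 1
#>   order 2 PCA: PC1 84.41%, 1 components > 1
#>   melody-bass correlations: 3 of 3 significant at alpha = 0.05

res$correlations[, c("order", "n", "r", "p", "strength")]
#>   order  n         r           p strength
#> 1     0 16 0.6964111 0.002725847 moderate
#> 2     1 16 0.6964111 0.002725847 moderate
#> 3     2 16 0.7344396 0.001195348   strong

res$interpretation[, c("order", "component", "variance_pct", "classification")]
#>   order component variance_pct classification
#> 1     0         1    85.747183         shared
#> 2     0         2     4.090775 voice-contrast
#> ...
```

Reading the output: the first principal component carries positive
loadings on every (unit, voice) variable — the statistical practice shared
by all pieces and both voices — while the second separates melody from
bass, the voice-specific profile the generator injected. The melody–bass
entropy correlation (r ≈ 0.70–0.73, p < 0.01 at 16 units) recovers the
generator's cross-voice uncertainty coupling; orders 0 and 1 coincide by
construction under the default window encoding (see the vignette). With
real scores, replace the corpus with
`loadCorpus("manifest.csv")` where the CSV lists
`path,piece_id,unit_id,mode` per movement.

All result tables can be written to disk (`runAnalysis(..., outDir =)`),
each stamped with a configuration hash; reruns are byte-identical.

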