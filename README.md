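# sovscore

Segment overlap scores for segmented state sequences.

Many biological sequences are naturally *segmented*: a protein
secondary-structure string is runs of helix (H), strand (E) and coil (C); a
genomic region partitioned by a TAD caller is runs of domain-body (D) and
boundary (B) bins. When a predicted segmentation is compared with a
reference, per-position accuracy (Q3/Q8, generally Q-k — the fraction of
identical positions) ignores whether the correct positions form contiguous
segments, yet contiguity is exactly what matters: a prediction scattering
ten isolated helix residues is far worse than one placing a ten-residue
helix slightly off its true boundaries. Segment overlap (SOV) scores fix
this by scoring maximal same-state runs against each other and granting a
bounded "allowance" for boundary variation.

`sovscore` implements, for any single-character state alphabet:

- **`q_score`** — per-position accuracy (Q3, Q4, Q8, ... depending on the
  alphabet);
- **`sov99`** — the normalized 1999 SOV definition, the long-standing
  standard in secondary-structure assessment;
- **`sov_refine`** — the refined SOV, whose allowance comes from a
  reference-wide budget and grows with every additional correctly
  assigned position, so a strictly better prediction always earns a
  strictly higher score, by an increasing increment.

## The scores

For each state *i* occurring in the reference, every overlapping pair
(s₁, s₂) of a reference segment s₁ and a same-state predicted segment s₂
contributes

    SOV(i) = 1/N(i) · Σ_{S(i)} [ (minov(s₁,s₂) + δ(s₁,s₂)) / maxov(s₁,s₂) · len(s₁) ]

where minov/maxov are the intersection and union sizes of the two
segments, N(i) sums len(s₁) once per overlapping pair plus once per
unoverlapped reference segment, and the overall score is the
N(i)-weighted mean of the SOV(i). The two SOV variants differ only in the
allowance δ:

- **SOV'99:** δ = min(maxov − minov, minov, ⌊len(s₁)/2⌋, ⌊len(s₂)/2⌋), an
  integer depending only on the pair;
- **SOV_refine:** each reference sequence gets a total budget
  δ(all) = λ · N_C / Σⱼ (len(sⱼ)/len(s_r))², growing with the number of
  states N_C and with fragmentation, and each pair receives
  δ = δ(all) · len(s₁)/len(s_r) · minov/maxov, clamped to maxov − minov.
  λ (default 1) tunes stringency; smaller λ is stricter.

Unequal-length pairs are compared with `sliding_best_score()` (maximum
score of the shorter sequence over all windows on the longer); TAD-style
interval lists become two-state strings with `intervals_to_states()`.

## Worked example

The canonical benchmark reference `CHHHHHHHHHHC` against the prediction
`CCCHHHHHHHHC` (the helix found, one residue short, edges shifted):

```r
library(sovscore)
score_pair("CHHHHHHHHHHC", "CCCHHHHHHHHC")
#>       method lambda     score
#> 1          q     NA 0.8333333
#> 2      sov99     NA 0.9444444
#> 3 sov_refine      1 0.9368192
```

Q3 = 0.833 counts 10/12 identical positions; both SOV scores are higher
because the single long helix overlap is what the measures reward. The
full decomposition:

```r
sov_refine("CHHHHHHHHHHC", "CCCHHHHHHHHC")
#> <sov_score> method: sov_refine (lambda = 1)
#>   overall: 0.937   Q: 0.833   length: 12   states: 2
#>   delta(all): 2.824
#>   state C: SOV = 0.680, N = 2 (2 pair(s), 0 unmatched)
#>   state H: SOV = 0.988, N = 10 (1 pair(s), 0 unmatched)
```

`worked_examples()` returns the full benchmark tables (eight three-state
and four four-state predictions with their expected scores); the test
suite recomputes every cell.

From a shell, the installed launcher scores files directly:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("scripts", "sov-score", package = "sovscore"))')
Rscript "$SCRIPT" --ref ref.txt --pred pred.txt --method all --lambda 1
Rscript "$SCRIPT" --tad-ref ren.bed --tad-pred caller.bed \
    --region 137800000-140280000 --bin-size 40000 --format json
```

TSV reports go to stdout (or `--out`); `--format json` adds the per-state
pair decomposition for auditing.

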