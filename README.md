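# markerAttn

Marker-gene cell type annotation for single-cell RNA-seq with a
pathway-masked attention classifier.

## What problem this solves, and for whom

Given a cells × genes count matrix and nothing else but a catalog of
marker genes per candidate cell type, `markerAttn` assigns every cell a
probability distribution over the types — no labelled reference cells,
no pre-trained atlas. It is aimed at analysts who have a marker list
(from the literature, from CellMarker/PanglaoDB-style resources, or
from a collaborator) and want annotations that come with an
*explanation*: alongside each call the classifier reports how much
attention it paid to each biological pathway, giving a per-cell,
per-pathway interpretability profile that can itself be clustered and
tested for signature pathways.

## The method

Three stages:

1. **Relevance scoring.** A raw association score `R_ij` between cell
   `i` and type `j` is computed from the markers. The default strategy
   weights each pooled marker `m` by its *cell type specificity*

   `S_m = 1 − (|M_m| − min|M|) / (max|M| − min|M|)`,

   where `|M_m|` is the number of types listing `m` (a marker private
   to one type scores 1, the most ubiquitous scores 0), and sets
   `R_ij` to the mean over type-`j` markers of the per-gene z-scored,
   library-normalized expression weighted by `S`. Five further
   strategies (expressed-marker counts, and cosine / logistic
   regression / sampled pseudo-cells in an external gene-embedding
   space) are available behind `scoreRelevance()`.

2. **Soft pseudo-labels and pretraining.** Each row of `R` is mapped
   onto the probability simplex (row softmax by default), giving soft
   pseudo-labels `L`. A classifier is pretrained to minimize
   `KL(L‖Y) = Σ_i Σ_j l_ij log(l_ij / y_ij)`. The classifier embeds the
   log-normalized expression into one token per pathway through a
   mask-constrained linear map (`W′ = W ⊙ M` with `M` the binary
   pathway-membership matrix, so a token can only read its member
   genes), prepends a trainable CLS token, applies one multi-head
   self-attention layer `A = softmax(QKᵀ/√d_k)`, `O = AV`, and feeds
   the CLS output row to a linear softmax head.

3. **Self-training.** The model's own full-data predictions at round
   `t` become the targets at round `t+1`
   (`KL(Y⁽ᵗ⁾‖Y⁽ᵗ⁺¹⁾)`, warm start), until fewer than 0.1% of argmax
   labels change.

The head-averaged CLS→pathway attention row is the cell's
interpretability profile; `clusterAttention()` and
`signatureAttentions()` turn profiles into subclusters and
per-subcluster pathway rankings (one-vs-rest Wilcoxon, BH-adjusted).

A seeded negative-binomial simulator (`simulateCells()`) with planted
types, markers, enriched pathways and type-structured gene embeddings
exercises the whole pipeline with no external data.

## Worked example

```r
library(markerAttn)

ds <- simulateCells(nCells = 400, nGenes = 200, nTypes = 4,
                    markersPerType = 8, nPathways = 12, seed = 7)
ds$markers
#> MarkerCatalog with 4 cell types
#>   markers per type: TYPE1 (8), TYPE2 (8), TYPE3 (8), TYPE4 (8)

res <- annotateCells(ds$expr, ds$markers, ds$pathways,
                     embedDim = 32, seed = 7)
res
#> AnnotationResult for 400 cells, 4 types
#>   predicted composition: TYPE1 (107), TYPE2 (83), TYPE3 (109), TYPE4 (101)
#>   self-training rounds: 1

rep <- classificationReport(ds$trueTypes, predictedTypes(res))
round(c(precision = rep$precisionMacro, recall = rep$recallMacro,
        macroF1 = rep$f1Macro, microF1 = rep$f1Micro), 3)
#> precision    recall   macroF1   microF1
#>     0.888     0.889     0.888     0.890
```

Against the planted ground truth, 89% of the 400 cells are labelled
correctly (micro-F1 = accuracy here), with balanced per-type quality
(macro metrics ≈ micro). The interpretability side:

```r
prof <- attentionProfiles(res)          # cells x pathways
cl <- clusterAttention(prof, seed = 7)  # Louvain on the SNN graph
sig <- signatureAttentions(prof, cl)
head(subset(sig, rank == 1))
#>    cluster    pathway statistic            p            q rank
#> 1        0 PW03_TYPE3  8.382462 5.202703e-17 3.121622e-16    1
#> 13       1 PW02_TYPE2 12.375522 3.572488e-35 4.286986e-34    1
#> 25       2 PW04_TYPE4 14.668905 1.027365e-48 1.232838e-47    1
```

Each attention subcluster's top-ranked signature pathway is a planted
type-enriched pathway: the classifier's attention concentrates on the
gene sets that define the types it predicts. (Attention subclusters are
coarser than the planted types — see the vignette for why the attention
view carries less information than the classification itself.)

A command-line wrapper with `simulate` / `relevance` / `annotate` /
`interpret` / `evaluate` subcommands ships in `inst/cli/markerattn.R`;
every run writes a `manifest.json` with the resolved configuration,
seeds and input checksums.

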