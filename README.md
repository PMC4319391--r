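# pascloud

Pathway activation scoring and signaling-pathway-cloud drug screening from
case-versus-control gene expression data.

## What it does

Two physiological states — an "enhanced" brain versus control, a treated
tissue versus untreated — can be distinguished by the set of signaling
pathways each state activates or represses. `pascloud` quantifies that
disturbance per pathway and turns the result into a drug-screening target:

1. **Pathway activation strength (PAS).** Every pathway member gene carries
   a signed activator/repressor role weight (ARR): positive for activators,
   negative for repressors. For a pathway *p* and a case sample,

   PAS*p* = Σ*n* ARR*np* · BTIF*n* · log₁₀(ECR*n*)

   where ECR*n* is the gene's expression in the case sample divided by its
   mean in the normalized control group, and BTIF*n* (beyond-tolerance
   interval flag) is 1 only when the ratio falls outside [2/3, 3/2] **and**
   the case level deviates from the control mean by more than two control
   standard deviations. PAS > 0 means the pathway is activated, PAS < 0
   repressed. The multiplicative counterpart, the signaling pathway cloud
   disturbance SPCD = Π[AGEL]ᵢ / Π[RGEL]ⱼ (activator levels over repressor
   levels), satisfies 10^PAS = SPCD when all role weights are ±1 and all
   flags pass.

2. **The signaling pathway cloud.** Pathways whose aggregate |PAS| exceeds a
   threshold, labeled activated/repressed — a transcriptomic fingerprint of
   the condition.

3. **Enrichment.** Gene lists of interest (e.g. genes whose mutation
   enhances cognition in animal models) are prioritized against the pathway
   database by a one-sided Fisher's exact test with Benjamini–Hochberg
   adjustment.

4. **Drug screening.** Each candidate drug gets its own PAS signature from
   treated-vs-untreated expression. Drugs are ranked by cosine similarity to
   the target cloud (**mimic**), to its reversal (**minimize**), or by the
   signed projection ratio (**exaggerate**, >1 = beyond-target amplitude).

A seeded synthetic-data generator plants known fold changes on pathway
members (log-normal baseline, activators ×f, repressors ×1/f), so the whole
chain is testable against closed-form ground truth without any downloads.

Intended users: computational biologists screening compound libraries
against a transcriptomic state — the motivating application is nootropic
discovery, but any case/control contrast works.

## Worked example

```r
library(pascloud)

db <- pathway_db(list(
  pathway("CAMP_AXONAL",    c("ADCY1", "PRKACA", "PDE4B"), c("act", "act", "rep")),
  pathway("IGF1R_SURVIVAL", c("IGF1R", "AKT1", "PTEN"),    c("act", "act", "rep"))))

m <- matrix(c(400, 380, 100, 110,  90,   # ADCY1  up ~4x in cases
              210, 190, 100,  95, 105,   # PRKACA up ~2x
               25,  30, 100, 105,  95,   # PDE4B  (repressor) down ~4x
              100, 105, 100,  98, 102,   # IGF1R  unchanged
              110,  95, 100, 101,  99,   # AKT1   unchanged
               98, 102, 100, 100, 100),  # PTEN   unchanged
            nrow = 6, byrow = TRUE,
            dimnames = list(c("ADCY1","PRKACA","PDE4B","IGF1R","AKT1","PTEN"),
                            c("enh1","enh2","ctl1","ctl2","ctl3")))
design <- group_design(case = c("enh1", "enh2"),
                       control = c("ctl1", "ctl2", "ctl3"))

prof  <- pas_profile(as_expression_matrix(m), design, db)
cloud <- build_cloud(prof)
round(prof$aggregate, 3)
#>    CAMP_AXONAL IGF1R_SURVIVAL
#>          1.454          0.000
cloud
#>    pathway_id      pas     label
#> 1 CAMP_AXONAL 1.453878 activated
```

The cAMP pathway scores 1.454: each member passes the tolerance filter
(ECR 4, 2.1 and 0.25 against fold bounds 3/2 and 2/3, deviations far beyond
2 control SDs) and contributes its signed log₁₀ ratio, e.g. +0.602 for the
4× activator and +0.602 for the 4×-down repressor; the mean over the two
case samples is 1.454. The untouched IGF1R pathway scores exactly 0, so the
cloud contains one activated pathway.

```r
drug  <- drug_signature("rolipram_like", c(CAMP_AXONAL = 1.1,  IGF1R_SURVIVAL = 0.05))
decoy <- drug_signature("decoy",         c(CAMP_AXONAL = -0.2, IGF1R_SURVIVAL = 0.9))
rank_drugs(list(drug, decoy), cloud, mode = "mimic")
#>   rank       drug_id score n_covered coverage zero_signal
#> 1    1 rolipram_like     1         1        1       FALSE
#> 2    2         decoy    -1         1        1       FALSE
```

The drug whose signature points the same way as the cloud ranks first.

## Command line

`inst/cli/pascloud.R` wraps the same functions:

```sh
Rscript inst/cli/pascloud.R simulate --out demo --n-decoys 9 --seed 5
Rscript inst/cli/pascloud.R pas --expr demo/expression.tsv \
    --design demo/design.tsv --pathways demo/pathways.gmt --out demo/run
Rscript inst/cli/pascloud.R screen --target-cloud demo/run/cloud.tsv \
    --library demo/drugs/manifest.tsv --pathways demo/pathways.gmt --mode mimic
Rscript inst/cli/pascloud.R enrich --genes list.txt --pathways demo/pathways.gmt
Rscript inst/cli/pascloud.R run --config cfg.yaml --out results
```

Pathways use a role-annotated GMT dialect, one pathway per line:
`id<TAB>description<TAB>GENE:act<TAB>GENE:rep:0.5 ...`.

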