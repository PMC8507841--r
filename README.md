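# TransporterTraits

Membrane transporter trait profiling for metagenome/metatranscriptome
time series.

Microbial uptake of organic matter and mineral nutrients happens through
membrane transporter proteins, and in a seasonal survey the abundance of
transporter genes per taxon and substrate is a trait-level readout of who
is equipped to take up what, and when. This package implements, as
tested R functions, the curation and analysis chain needed to produce
that readout from ORF-level annotation and count tables:

1. **Family screen** — candidate transporter protein families are found
   by case-insensitive text search over PFAM/TIGRFAM/COG-style family
   metadata (default terms: `transport`, `efflux`, `uptake`, `symport`,
   `antiport`).
2. **Transport clusters** — families are nodes; every unordered pair of
   candidate families co-annotating the same reviewed cross-reference
   entry or the same operon is an edge. Nodes with degree > 6 (generic
   "hub" domains such as ubiquitous ATP-binding cassettes) are removed
   in a single pass on input degrees, and transporters are the connected
   components of the pruned graph — each cluster representing the full
   subunit set of one transporter.
3. **Annotation** — each cluster gets one of nine substrate categories
   (curated override, else majority vote of TIGRFAM-role hints, which
   take precedence, else GO hints, else excluded) and a transport class
   (metal / toxin exporter / utility exporter / importer / other) from
   ordered keyword rules, plus secretion type for toxin exporters.
4. **Quantification** — TPM normalisation
   `tpm(i,s) = 1e6 · (c(i,s)/L(i)) / Σ_j c(j,s)/L(j)` (columns sum to
   10⁶), single-cluster ORF assignment with source priority
   TIGRFAM > COG > PFAM, and the *abundant transporter* filter: relative
   abundance strictly > 0.5 % of total transporter TPM in at least one
   sample of either dataset (union over MG and MT).
5. **Taxonomy** — contigs vote a lowest common ancestor from their ORFs
   (rank-descending strict majority), the voted path propagates back to
   all ORFs, and abundance aggregates into a taxon × category × sample
   tensor (with domain groupings that report Cyanobacteria apart from
   the remaining Bacteria).
6. **Seasonal ecology** — per-taxon composition stability, succession
   peak ordering, MG–MT gene-abundance/expression correlation on matched
   dates, and a Spearman screen against environmental variables
   (|ρ| > 0.5, p < 0.05; exact permutation p-values by full enumeration
   for n ≤ 8, valid under ties).

A first-class synthetic-data module (`simulateReference`,
`simulateCommunity`) plants known cluster structure, hub families,
per-taxon substrate profiles, Gaussian seasonal peaks and
environment-linked abundances, so every stage is validated by exact or
bounded recovery of planted truth. See the vignette
(`vignettes/transporter-traits.Rmd`) for the model, the open design
choices and the known limitations.

## Worked example

```r
library(TransporterTraits)

cats <- substrateCategories()
specs <- c(lapply(1:9, function(i)
             clusterSpec(sprintf("PC%02d", i), 1 + i %% 3, cats[i], "importer")),
           list(clusterSpec("PC10", 2, "cation", "metal"),
                clusterSpec("PC11", 3, "anion", "exporter_toxin")))
ref <- simulateReference(specs, nDecoyFamilies = 15, nHubs = 1,
                         hubDegree = 7, seed = 1)
screenFamilies(ref$families)
#> FamilyScreen with 24 candidate families
#>   terms: transport, efflux, uptake, symport, antiport (substring match)
#>   per source: COG=8, PFAM=5, TIGRFAM=11
```

The 24 candidates are the 23 planted transporter families plus the
planted hub; the 15 decoys carry no screen keyword and are dropped. A
three-taxon seasonal community then runs through the whole chain:

```r
taxa <- list(
  taxonSpec("Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales", 100, 25, 1,
            c(cation = 0.5, amino_acids_peptides_ammonium = 0.27, carbohydrate = 0.23)),
  taxonSpec("Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales", 160, 25, 1,
            c(carbohydrate = 0.4, phosphonate = 0.3, anion = 0.3)),
  taxonSpec("Bacteria;Proteobacteria;Gammaproteobacteria;Cellvibrionales", 220, 30, 1,
            c(anion = 0.4, amino_acids_peptides_ammonium = 0.6)))
comm <- simulateCommunity(communitySpec(taxa, depth = 1e5), ref$truth, seed = 1)
res <- runTransporterPipeline(ref, comm)

res$clusters
#> TransportClusterSet with 11 clusters ( 23 families )
#>   annotated: 11 | excluded: 0
#>   classes: exporter_toxin=1, importer=9, metal=1
res$abundance$MG
#> ClusterAbundance [MG]: 7 clusters x 33 samples
#>   abundant (> 0.50% in >=1 sample): 7 clusters
```

The hub was pruned (11 clusters, 23 families, exactly the planted
partition); 7 of the 11 clusters receive reads because the three taxa
only use 7 categories. Succession and trait stability come from the
taxon × category × sample tensor:

```r
successionSummary(res$tensor$MG, comm$samples$date[comm$samples$dataset == "MG"])
#>             taxon peak_date peak_value
#>  Flavobacteriales        60   899062.1
#>   Rhodobacterales       161   755570.9
#>   Cellvibrionales       327   902373.8

st <- compositionStability(res$tensor$MG, floor = 1000)
round(st$mean["Flavobacteriales", st$mean["Flavobacteriales", ] > 0], 3)
#> amino_acids_peptides_ammonium  carbohydrate  cation
#>                         0.269         0.231   0.500
round(st$stability, 3)
#>  Cellvibrionales Flavobacteriales  Rhodobacterales
#>            0.009            0.018            0.014
```

The planted succession order (Flavobacteriales → Rhodobacterales →
Cellvibrionales) is recovered — note the peak *dates* are shares of a
compositional total, so they shift towards the panel edges relative to
the planted Gaussian centres (100, 160, 220) while the order is
preserved. The recovered Flavobacteriales composition matches the
planted 0.50/0.27/0.23 profile to within sampling error, and the
stability scores near 0 reflect the planted constancy of each taxon's
substrate profile over the year.

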