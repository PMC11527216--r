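# refcov

Audit reference-sequence availability per organism and per DNA-barcode
locus across sequence databases.

## The problem

eDNA metabarcoding and species-specific qPCR assays both stand or fall
on reference sequences: pre-labeled database entries that let you
identify unknown reads or design primers against target and non-target
taxa. For many organisms, no reference sequence exists at the locus you
care about, and discovering that usually means days of manual searches
across NCBI Nucleotide, BOLD, and curated metabarcoding databases.
`refcov` automates the audit. Given a list of organisms and barcode
loci (CO1, 16S, 18S, 12S, FITS, PITS, trnL, ...), it queries a
pluggable record source and produces:

- the **Coverage Matrix** `C`, with `C[o, b]` = number of reference
  sequences for organism `o` at barcode group `b` (zeros reveal
  reference gaps; a failed search is `NA`, never `0`);
- per-barcode **summary rows** `(n_b, 100·n_b/Σn, |{o : C[o,b] > 0}|,
  |{o : C[o,b] = 0}|)` — sequences found, percentage share, organisms
  covered, organisms missing;
- **rank-fallback rows**: when `C[o, b] = 0` for a species, counts at
  its genus, family and order (subtree semantics over the taxonomy
  backbone); a species missing from the backbone is flagged
  `UNREGISTERED` and never searched at broader ranks;
- deduplicated per-barcode **FASTA bundles** (BOLD records whose
  GenBank cross-reference is already in the NCBI result set can be
  removed before download);
- the literal **Entrez search statements** used, exportable for
  validation in NCBI's own web interface.

Record sources: live NCBI Nucleotide (E-utilities), the BOLD public
API, local CRUX-style per-barcode reference databases
(`<barcode>.fasta` + `<barcode>_taxonomy.txt`), and offline TSV
snapshots. A seeded synthetic-snapshot generator with planted coverage
structure makes the whole workflow testable without a network.

## Worked example

Audit the bundled demo world (11 invasive California species; the demo
snapshot plants CO1 coverage for five of them and 16S for six):

```r
library(refcov)

plan <- demo_plan()
snap <- generate_snapshot(plan)
q    <- read_query_csv(system.file("extdata", "example_query.csv",
                                   package = "refcov"))
cm   <- build_coverage_matrix(snap, resolve_names(q$organisms),
                              groups_for_barcodes(c("CO1", "16S")),
                              enable_fallback = TRUE)
print(cm)
summary(cm)
```

```
Coverage matrix: 11 organisms x 2 barcodes
                             CO1 16S
Eleutherodactylus coqui       31   2
Lithobates catesbeianus        0   3
Xenopus laevis                38   3
Ctenopharyngodon idella       12   2
Dreissena polymorpha           0   0
Dreissena bugensis             0   0
Eriocheir senensis             0   0
Euwallacea kuroshio            0   0
Euwallacea whitfordiodendrus   0   0
Pomacea canaliculata           9   1
Potamopyrgus antipodarum       7   1
  Euwallacea whitfordiodendrus: UNREGISTERED
27 fallback row(s) at broader ranks
 barcode n_sequences pct_of_total n_organisms_covered n_organisms_missing
     CO1          97           89                   5                   6
     16S          12           11                   6                   5
total sequences: 109; organisms detected: 6 of 11
```

Reading it: CO1 holds 97 of the 109 sequences (89.0%) but covers only
5 of 11 organisms; 16S covers 6. *Lithobates catesbeianus* has no CO1
records at species rank, so fallback rows report its genus
(*Aquarana* — the backbone's placement, with a drift warning since the
binomial says *Lithobates*), family and order counts. *Euwallacea
whitfordiodendrus* is not registered in the backbone: its row stays
all-zero, and no broader search is attempted. `write_matrix_csv()`
renders fallback rows beneath their organism as `genus: Aquarana` etc.

Build an Entrez statement you can paste into NCBI's web interface:

```r
build_entrez_term("Xenopus laevis", default_barcode_groups()$CO1,
                  filters = filter_spec(400, 700))$text
#> ("Xenopus laevis"[ORGN]) AND ("CO1"[GENE] OR "COI"[GENE] OR ... )
#>   AND ("400"[SLEN] : "700"[SLEN])
```

## Command line

```sh
Rscript inst/cli/refcov synth --out-dir demo --seed 77
Rscript inst/cli/refcov audit --db snapshot --source-path demo/snapshot.tsv \
    --query inst/extdata/example_query.csv --out-dir demo/out
Rscript inst/cli/refcov fetch --db snapshot --source-path demo/snapshot.tsv \
    --query inst/extdata/example_query.csv --min-len 400 --out-dir demo/out
```

`audit` writes `coverage_matrix.csv`, `summary.csv`,
`search_statements.txt` and `run_log.tsv` (exit 2 if any cell failed);
`fetch` writes `sequences.zip` + `manifest.csv` (exit 3 when nothing
matched); `dedupe` splits a BOLD snapshot into kept/removed against an
NCBI snapshot. Live runs need `--db ncbi --email you@example.org` (an
API key raises the request rate from 3/s to 10/s) or `--db bold`.

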