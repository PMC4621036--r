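# domex — detecting discontinuous protein domains by segment assembly

Sequence-based domain boundary predictors split a protein chain into
contiguous segments, but many structural domains are *discontinuous*: two
segments far apart in sequence fold together into one domain (CATH writes
such an assignment as `1-156|342-393`, and ~15% of classified domains look
like this). Boundary predictors alone cannot say which non-adjacent
segments belong together. `domex` closes that gap for anyone running a
boundary predictor — structure-prediction pipelines, domain-annotation
workflows — by testing every non-adjacent segment pair against a library
of known single-domain sequences.

## Method

Each non-adjacent segment pair (both segments ≥ 40 residues) is
concatenated into a putative domain *Q* and searched against the library.
A template hit *T* is accepted when it passes four filters:

* **Template-similarity score** — TS = *s·h·l*, with *s* the alignment
  identity, *h* = min(*E*₀, −log₁₀ *E*)/*E*₀ the normalised E-value
  (*E*₀ = 10), and *l* a sigmoid in the alignment coverage *c*
  (0 for *c* ≤ 1/3, 1/(1 + (1/(3*c* − 1))⁵) above).
* **Symmetry index** — the alignment is split at the junction between the
  two segments; SI = ‖(*s_p*, *c_p*) − (*s_q*, *c_q*)‖. A genuine joint
  template matches both segments symmetrically (small SI); a template
  matching only one segment scores near √2.
* **Length error** — *e* = |*L_T* − *L_Q*|/*L_Q* < 0.2.
* **Cutoff constraint** — the TS and SI cutoffs are tied by a
  one-parameter piecewise function *T_SI* = *f*(*T_TS*, *b*) keeping the
  SI cutoff in [0.1, 0.3]; a single parameter *b* (default 0.3) trades
  recall against precision.

Hits on sequence-derived (Pfam-like) templates additionally need a
profile–profile alignment score below −1.90 when *b* < 0.5; among passing
hits and among conflicting candidates the lowest PPA-score wins. See the
methods vignette (`vignettes/discontinuous-domains.Rmd`) for the score
definitions, defaults and design choices.

## Worked example

Everything below runs offline: the synthetic-fixture generator builds a
library and queries with known ground truth.

```r
library(domex)

fx <- generate_fixtures(fixture_spec(seed = 7, n_chains = 6))
fx$library
#> Domain library: 23 records (13 STRUCTURE, 10 SEQUENCE)
#>   lengths: 135-233 residues

# chain001 carries a planted discontinuous domain (segments 2 and 4)
b <- fx$boundaries$boundary[fx$boundaries$chain_id == "chain001"]
b
#> [1] 101 179 269

pred <- predict_domains(fx$queries[["chain001"]], b, fx$library,
                        domex_config(), chain_id = "chain001")
pred
#> Chain chain001 (356 residues): 3 domain(s)
#>   1: 1-101
#>   2: 102-179|270-356  [discontinuous]  template=cath|tmpl_chain001
#>   3: 180-269

str(Filter(function(d) d$discontinuous, pred$domains)[[1]]$scores)
#> List of 6
#>  $ ts_score : num 0.852
#>  $ h        : num 1
#>  $ l        : num 0.97
#>  $ si       : num 0.0354
#>  $ e        : num 0
#>  $ ppa_score: num -1.93
```

Reading the scores: the assembled pair aligns to its template with
TS-score 0.85 (identity ≈ 0.88 at full coverage, E-value below 1e−10 so
*h* = 1, coverage factor 0.97), the two segments match the template
symmetrically (SI 0.035), the lengths agree exactly (*e* = 0), and the
profile–profile score −1.93 is below the −1.90 cutoff. Segments 1 and 3
found no joint template and are reported as continuous domains.

Real inputs follow the same shapes: a query FASTA, a boundary TSV with
columns `chain_id`/`boundary` (1-based, "break after residue"), and a
library FASTA whose headers carry source prefixes (`cath|`/`scop|` for
structure-derived records, `pfam|` for sequence-derived; see
`read_domain_library()` to customise the rules, `dedup_library()` for the
90% redundancy filter). `run_domex()` drives whole files and writes
TSV/JSON reports; a command-line wrapper with the same functionality
ships at `inst/cli/domex.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/domex.R", package="domex"))') \
    predict --query queries.fasta --boundaries boundaries.tsv \
    --lib LIBDIR --out OUT/
```

Search is pluggable: the default `builtin_backend()` (BLOSUM62
Smith–Waterman with Karlin–Altschul E-values) needs no external binaries;
`psiblast_backend()` runs a two-stage profile search through NCBI
`psiblast` for remote homologs.

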