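# taxmeon — taxonomic-concept graphs for species checklists

Scientific names are the keys by which biological information is indexed,
and they are unstable: synonyms multiply, species move between genera,
taxa are lumped and split, and the same name can mean different things in
different checklists. `taxmeon` is an R package for curators and
biodiversity informaticians who need to reconcile species checklists and
publish them as machine-readable linked data. It represents each
checklist entry as a *taxonomic concept* — a scientific name plus its
circumscription inside one list, identified by an HTTP URI — following the
TaxMeOn meta-ontology, and provides:

* **Name assembly** — binominal/trinominal combinations with authorship
  built by traversing the checklist hierarchy
  (`Arhopalus ferus (Mulsant, 1839)`; botanical style `(L.) A.J. Scot`),
  plus author-abbreviation canonicalisation (`L.` = `Linn.` = Linnaeus)
  and normalised name keys for matching.
* **Concept mapping** — automatic species-level congruence for taxa
  sharing name and authorship; higher-taxon alignment always derived from
  species content (congruent ⟺ equal species sets, part-of ⟺ proper
  containment, overlap otherwise); closure and contradiction detection
  under the relation algebra (congruent: symmetric + transitive; part-of:
  directed + transitive; overlap: symmetric, *not* transitive); coarse
  `TaxonGeneral` grouping kept separate from manual assertions.
* **Change detection** — diffing checklist versions into reified change
  events (genus transfers, lumps, splits, status changes, additions,
  removals) whose before- and after-concepts are linked by the algebra;
  the URI-duplication rule for dynamic lists (a change duplicates the
  species and their immediate genus, never the upper classification);
  concept timelines across versions; nomenclatural-priority warnings.
* **Identifiers** — seeded, collision-checked HTTP URI minting
  (`BASE/CHECKLIST_ID/pNUMBER`) and LSID parsing/formatting
  (`urn:lsid:authority:namespace:object[:revision]`).
* **I/O** — a checklist CSV dialect, Darwin Core Archive taxon cores
  (with vernacular extension), deterministic TaxMeOn Turtle output and a
  reader that round-trips it; mappings as 5-column TSV; diffs as JSON
  lines.
* **Synthetic data** — a seeded checklist generator and revision mutator
  with ground-truth events, driving parameter-recovery experiments.

## Worked example

Two packaged long-horn beetle checklists classify the same three species
differently: in 1992 *pubescens*, *revestita* and *aethiops* all sit in
*Leptura* and *Pedostrangalia* is a synonym; in 2011 *Pedostrangalia* is
valid and carries *pubescens* and *revestita*.

```r
library(taxmeon)

a <- exampleChecklist("beetles_1992")
b <- exampleChecklist("beetles_2011")
a
#> Checklist 'cerambycids1992': 5 taxa
#>   genus: 2, species: 3

pub <- Filter(function(t) t@label == "pubescens", taxa(a))[[1]]
assembleCompleteName(pub, a)
#> [1] "Leptura pubescens Fabricius, 1787"
```

The same name key (`pubescens|Fabricius|1787`) identifies the species in
both lists even though its genus — and hence its complete name, now
parenthesised — changed:

```r
pub2 <- Filter(function(t) t@label == "pubescens", taxa(b))[[1]]
assembleCompleteName(pub2, b)
#> [1] "Pedostrangalia pubescens (Fabricius, 1787)"

mapSpecies(a, b)[[1]]
#> <http://example.org/onto/cerambycids1992/p429244774> congruent <http://example.org/onto/cerambycids2011/p301440197> [ostensive, automatic]
```

Diffing the versions classifies the revision — two genus transfers and the
resurrection of *Pedostrangalia* from synonymy — and the events give each
concept a timeline:

```r
ev <- diffChecklists(a, b)
vapply(ev, function(e) e@changeType, character(1))
#> [1] "status_change"  "genus_transfer" "genus_transfer"

temporalOrder(Corpus(list(a, b), events = ev), pub@uri)
#>  when status                                                uri
#>  1992  valid  http://example.org/onto/cerambycids1992/p70390104
#>  2011  valid http://example.org/onto/cerambycids2011/p271871375
```

`writeTurtle(Corpus(list(a, b), events = ev), "beetles.ttl")` serialises
the whole graph — taxa typed as `taxmeon:TaxonInChecklist` and their rank
class, hierarchy, statuses, authorship, `completeTaxonName` literals,
mapping predicates and change instances — deterministically;
`readTurtle()` reconstructs it.

The other packaged example (`aus_t0` / `aus_t1`) is a dynamic list in
which *cus* is synonymised under *bus*: the diff yields a single lump
event whose old concepts are `part_of` the enlarged surviving concept, and
`applyChange()` demonstrates the URI-duplication rule (exactly three new
URIs: both species and their genus).

See `vignettes/taxonomic-concept-graphs.Rmd` for the model, the design
decisions and the limits of what the synthetic experiments show.

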