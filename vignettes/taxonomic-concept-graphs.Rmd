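---
title: "Modelling species checklists as taxonomic-concept graphs"
author: "taxmeon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species checklists as taxonomic-concept graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmeon)
```

## The problem

Scientific names are the index keys of the life sciences, and they are
unstable keys. One taxon may carry several names (synonyms), one name may
attach to several circumscriptions over time, and revisions move species
between genera, merge taxa (lumps, where the older name survives under
nomenclatural priority) and divide them (splits). A species checklist
freezes one author's view at one moment; reconciling several checklists —
or several versions of one — therefore requires reasoning about *taxonomic
concepts*, not name strings.

This package represents checklists as graphs of concepts in the TaxMeOn
meta-ontology's vocabulary: each record (class `TaxonInChecklist`) couples
a uninomial name with its concept inside one checklist, hierarchy is
expressed with `isPartOfHigherTaxon`, synonymy with `hasNonvalidName`, and
concepts are linked within and across checklists with a small relation
algebra. Identity is an HTTP URI per checklist: the same scientific name
deliberately receives a *different* URI in every static checklist, so that
alternative classifications can coexist and a concept can be cited "as of"
a particular list.

## The relation algebra

Concept mappings use four relations, with the logical properties that drive
the closure engine (`closeMappings`):

| relation     | meaning                         | properties                |
|--------------|---------------------------------|---------------------------|
| `congruent`  | A = B                           | symmetric, transitive     |
| `part_of`    | A properly contained in B       | directed, transitive      |
| `overlaps`   | proper partial intersection     | symmetric, not transitive |
| `associated` | undetermined connection         | inert                     |

Two further rules close the composition of congruence with containment
(A ≅ B, B ⊂ C ⟹ A ⊂ C, and symmetrically). Overlap is never propagated:
knowing that A and B share something and B and C share something says
nothing about A and C. `associated` exists precisely so that curators
without the expertise to classify a connection can still record one; it
takes no part in inference. Each relation also carries a *mode* —
ostensive (membership-based) or intensional (character-based). Checklists
enumerate members, so the ostensive mode is the default for automatic
mapping; the mode is metadata only and never alters the algebra, because
the two modes share identical logical properties. `validateMappings`
closes a mapping set and flags the three possible inconsistencies:
congruent+part_of on one ordered pair, containment in both directions, and
congruent+overlaps.

Species concepts in different checklists are matched automatically when
they share a *name key*: the lower-cased epithet, the canonicalised
first-author surname and the year of description. The genus is excluded on
purpose — a genus transfer changes the binominal combination but not the
concept. Author canonicalisation uses a packaged, user-extensible
abbreviation table (e.g. `L.` and `Linn.` both stand for Linnaeus); only
attested equivalences ship as defaults. When a key matches more than one
candidate (homonyms), no congruence is asserted; `associated` suggestions
are emitted instead.

Higher taxa are never matched by name. Their alignment
(`alignHigherTaxa`) is always derived from species content projected
through the species congruences: equal sets give `congruent`, proper
containment `part_of`, remaining intersection `overlaps`. A species
recorded in only one region demotes a genus pair from congruent to
part_of — this conflation of taxonomy with regionality is inherent to the
method and is the reason the mode is recorded as ostensive. Alignment only
compares taxa of equal rank; cross-rank containment can be asserted
manually but is never inferred, since the species-content rule is defined
for taxa immediately above the species level.

`autoMapGeneral` provides the coarsest layer: one abstract `TaxonGeneral`
instance per name key, grouping every checklist-level taxon that shares
name and authorship. These machine groupings are kept apart from manual
assertions (provenance flags) so downstream consumers can rank by
reliability.

## Change over time

Two regimes are supported, mirroring how checklists are actually
published. **Static** lists are dated by their publication year; diffing
two versions (`diffChecklists`) matches records by name key and classifies
the differences: genus transfers (same key, different genus; old and new
concept linked congruent), lumps (valid names turned synonyms, grouped by
their accepted name; every old concept becomes part of the enlarged
surviving concept), splits (a species-group synonym promoted to valid
while its former accepted name persists; each new concept is part of the
old), status changes, additions and removals. Each detected change is
reified as an instance (`ChangeEvent`) carrying the before-state, the
after-state, the concept relations between them and the date — so a
machine can see *that* and *how* a taxonomy changed, and a concept can be
referenced at a particular time. The alternative representation
(relation-as-instance with time stamps) is noted as an extension hook but
not implemented.

Three classification choices were genuinely open and were resolved as
follows. A higher taxon rising from synonymy (as *Pedostrangalia* does in
the worked beetle example) is a status change, not a split: higher-taxon
circumscription is a matter of species content and is handled by
alignment. A species-group synonym promoted to valid is a split only when
its former accepted name survives as valid — that explicit link is what
makes the reversed containment unambiguous; silent splits (same name,
narrowed concept, no synonymy evidence) are undetectable from checklists
and out of scope. In a lump, the surviving name's own old concept is
linked `part_of` the new one rather than `congruent`, because the concept
grew; the congruent alternative is defensible and is noted here as such.

Nomenclatural priority is checked on every detected lump: the surviving
valid name should be the older one. Violations warn rather than error,
because published checklists do occasionally override priority.

**Dynamic** lists carry time stamps on every status. `applyChange`
implements the URI-duplication rule: a change touching a species mints new
URIs for the affected species *and their immediate genus* (preserving the
lower-level name combinations), while everything above the genus keeps its
URI to avoid an explosion of identifiers. Old records are retained, so the
full history remains addressable; `temporalOrder` walks the event links
and returns a concept's versions sorted by year (static) or time stamp
(dynamic), with a stable URI tie-break.

## Identifiers

Data URIs follow `BASE/CHECKLIST_ID/LOCAL_ID` with `LOCAL_ID` of the form
`p<NUMBER>`, where the number is randomly generated, globally unique
within the corpus session, and reproducible from a seed (`uriMinter`). A
random draw with collision checking, rather than a counter, avoids
embedding creation order in identifiers. Whether uniqueness should be
per-checklist or global is not fixed by the scheme; the minter enforces
global uniqueness, the stricter and safer reading. The default base is a
neutral example domain: the ontology's published production namespace
belongs to its operators, and users must set their own base before
publishing. LSIDs (`urn:lsid:authority:namespace:object[:revision]`) are
parsed positionally as printed — some real identifiers omit the
conventional namespace segment, and a semantic parser would reject them.
LSID network resolution is out of scope by design.

## RDF serialisation

`writeTurtle` emits the model with the TaxMeOn vocabulary namespace for
every class and property the ontology names (`TaxonInChecklist`,
`isPartOfHigherTaxon`, `hasStatus`, `occursInChecklist`,
`hasNonvalidName`, `completeTaxonName`, `completeAuctorumString`,
`auctorumYear`, `hasVernacularName(Status)`, `hasNomenclaturalCode`,
`publishedIn`/`publishedOriginallyIn`, `isAssociatedWithTaxon`, ...);
Dublin Core covers bibliographic fields. The shipped vocabulary is a
documented subset: the full ontology's class roster is larger than the
set of terms its description enumerates, and only named terms are used.
Among the mode-specific mapping properties only the intensional congruence
(`congruentWithTaxonInt`) is attested by name; the Int/Ost variants of the
other relations are formed by analogy (`partOfTaxonOst`,
`overlapsWithTaxonInt`, ...). Every taxon is typed both as
`TaxonInChecklist` and as its rank class, and a human-oriented
`completeTaxonName` literal (e.g. `"Arhopalus ferus (Mulsant, 1839)"`) is
generated by the same hierarchy traversal that users call directly.

Numerical and structural choices: the writer emits no blank nodes
(status, authorship, publication and vernacular hubs get fragment URIs
derived from the taxon URI), so graph isomorphism reduces to canonical
triple-set equality (`canonicalTriples`) and the output is byte-identical
across runs given the same URI seed — subjects, predicates and objects are
sorted canonically. The reader accepts the emitted subset plus common
hand-written variants, skips unknown predicates with one summarising
warning, and treats malformed input as a parse error. One representational
limit is documented rather than worked around: mapping provenance
(manual/automatic) is not reified in RDF, so it is restored as "manual" on
read, and a relation triple whose endpoints coincide with a change event's
before/after sets is attached to that event rather than kept standalone.

The rank vocabulary is a fixed, ordered eleven-rank subset
(kingdom…subspecies) rather than the external 61-class TDWG rank ontology:
no download dependency, extensible via configuration. Rank monotonicity
along parent chains is a warning, not an error, because real lists skip
and occasionally invert ranks. Parenthesised authorship is stored as a
flag rather than derived, since checklists rarely record the original
genus. Multiple zoological authors are joined with `" & "`; trinominal
rendering appends the subspecies epithet to the binominal rule — both are
extrapolations beyond the attested single-author, binominal examples and
are flagged as such. Botanical authorship renders as `"(orig) comb"`
without years, zoological as `"Author, Year"`.

## The synthetic generator

`generateChecklist` emulates the regime in which name-based reconciliation
is exact: unique name keys (pronounceable syllable names with collision
checking), authorship years uniform on 1758–2000, a configurable fraction
of species wired as synonyms of valid congeners, hierarchies of genera and
species. A positive synonym rate guarantees at least one synonym, since a
small list can otherwise draw none and a revision that promotes a synonym
would be unsupported. `mutateChecklist` injects a requested number of
transfers, lumps (always priority-respecting: the older name survives —
the priority-warning path is exercised by a deliberately violating
hand-built fixture in the tests), splits, additions and removals into
disjoint sets of eligible taxa, and returns the ground truth events. The
recovery experiment — fifty seeded revisions with 2 transfers, 1 lump,
1 split, 2 additions and 1 removal on checklists of 5 genera and 3–6
species each — is the package's core correctness property: the diff must
recover 100% of injected events with correct types.

What the generator does **not** emulate bounds what the tests show:
misspelled or variantly abbreviated names beyond the packaged table,
ambiguous homonym-rich floras, lists with missing authorship, rank-skipping
hierarchies, and concept changes that leave no nomenclatural trace. On
such data the name-key match degrades gracefully (ambiguities are withheld
and reported, not guessed), but recovery is necessarily below 100%; the
probabilistic/fuzzy matching that real dirty data would need is explicitly
out of scope.

## Problem sizes

The shipped experiments use deliberately small instances: the two worked
examples (5 + 5 and 3 + 3 records), 200 random mapping graphs of at most 8
nodes for the closure-vs-oracle property, 100 random genus pairs for the
alignment oracle, 50 synthetic revisions for recovery, and 12 corpora for
the RDF round trip. These sizes make every property checkable exhaustively
against brute-force oracles; nothing in the implementation is specific to
them, and the corpus-scale figures reported for the production deployment
of the ontology (tens of checklists, tens of thousands of names, millions
of triples) are not reproduced here because those source checklists are
not redistributable.

## Limitations

* Intensional (character-based) inference is representable but never
  inferred; no morphology is modelled.
* Splits without explicit synonymy evidence are undetectable.
* Diffing is pairwise; longer version chains are diffed stepwise.
* Nomenclatural-act validation (gender agreement, Latin grammar) and
  free-text name parsing are out of scope: input formats carry name parts
  separately, and the DwC-A reader parses only the regular authorship
  citation styles.
* The Turtle reader covers the emitted TaxMeOn subset, not arbitrary RDF;
  blank-node graphs from other tools are not understood.
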