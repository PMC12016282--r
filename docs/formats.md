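# File formats

All files are plain tab-separated text. Readers reject malformed input;
every writer/reader composition is the identity on valid data.

## Taxonomy dump (NCBI dialect)

`nodes.dmp`: pipe-delimited rows, only the first three fields consumed.

```
1	|	1	|	root	|
1763	|	1762	|	species group	|
```

- field 1: taxid (positive integer)
- field 2: parent taxid (the root is its own parent; exactly one such row)
- field 3: rank, one of `root, domain, kingdom, phylum, class, order,
  family, genus, species-group, species, strain, no-rank` (NCBI spellings
  `superkingdom`, `species group`, `no rank`, `subspecies` are accepted
  and normalized)

`names.dmp`: `taxid | name | unique-name | name class |`; only rows whose
class is `scientific name` (or rows with fewer than four fields) attach a
name. Nodes without a name are called `taxid:<id>`.

## Kraken report

Six tab-separated columns, one row per taxon with a non-zero clade count,
depth-first, children ordered by descending clade count then ascending
taxid. An optional leading `unclassified` row uses taxid 0 and code `U`.

```
 52.63	10	2	R	1	root
 42.11	8	0	G	2	  Mycogenus
 42.11	8	8	S	3	    Myco species
```

- col 1: percent of total reads in the clade, `%6.2f`
- col 2: clade count (reads at this node or any descendant)
- col 3: direct count (reads at exactly this node)
- col 4: rank code: `R D K P C O F G S` for canonical ranks; intermediate
  nodes (species groups, strains, unranked nodes) use the nearest
  canonical ancestor's letter plus the step count, e.g. `G1` for a
  species group directly under its genus, `S1` for a strain under its
  species
- col 5: taxid
- col 6: name, indented two spaces per tree depth

Invariant (validated on read): `clade(t) == direct(t) + sum of
clade(children(t))`.

## K-mer distribution file

Header line carrying k and r, a column-name line, then one row per
(genome, ancestor node) with a non-zero window count:

```
# k=31 r=75
genome_taxid	node_taxid	node_rank	window_count	total_windows	fraction
5	4	species-group	3776	3926	0.96179317371370354
5	5	species	150	3926	0.038206826286296486
```

- `window_count`: length-r windows of the genome classified to the node
- `total_windows`: `L - r + 1` summed over contigs of length >= r
- `fraction`: `window_count / total_windows`, serialized at full
  precision (`%.17g`); counts are the source of truth and the reader
  rejects files whose fraction column disagrees with `count/total`

## Abundance output

```
name	taxonomy_id	taxonomy_lvl	kraken_assigned_reads	added_reads	new_est_reads	fraction_total_reads
```

`kraken_assigned_reads` are the classifier's reads at or below the taxon
(after strain roll-up); `added_reads` are redistributed in from higher
nodes; `new_est_reads = kraken_assigned_reads + added_reads` holds exactly
on every written row (estimates are rounded half-to-even to integers at
output only); `fraction_total_reads` is `new_est / total reads` to five
decimals.

## FASTA

Standard multi-record FASTA; record ids are the first
whitespace-delimited header token; sequences are uppercased and `U`
mapped to `T` on input. The `build` subcommand pairs the FASTA with a
two-column `seqid<TAB>taxid` map file; multiple sequences mapping to one
taxid become contigs of a single genome.
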