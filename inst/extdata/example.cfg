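# Example scenario: intermediate population with an egg bank and
# moderate migration, neutral loci only.
K = 2e4        # carrying capacity (individuals)
M = 10         # immigrant individuals per sexual generation
r = 0.3        # clonal growth rate (days^-1)
F = 1          # founding diapausing eggs per locality
n = 5          # neutral marker loci
s = 0          # selected loci (neutral scenario)
y = 200        # sexual generations
bank = on
replicates = 10
seed = 1
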