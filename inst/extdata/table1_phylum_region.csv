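phylum,region,n_occurrences,n_species
Annelida (Polychaeta),tropical,0,0
Annelida (Polychaeta),subtropical,695,191
Arthropoda (Crustacea),tropical,4,3
Arthropoda (Crustacea),subtropical,317,162
Brachiopoda,tropical,0,0
Brachiopoda,subtropical,10,3
Bryozoa,tropical,0,0
Bryozoa,subtropical,17,8
Cnidaria,tropical,46,32
Cnidaria,subtropical,1705,121
Echinodermata,tropical,13,10
Echinodermata,subtropical,277,72
Mollusca,tropical,19,15
Mollusca,subtropical,717,314
Nematoda,tropical,0,0
Nematoda,subtropical,49,26
Porifera,tropical,0,0
Porifera,subtropical,273,74
Sipuncula,tropical,0,0
Sipuncula,subtropical,25,7
Total,tropical,82,60
Total,subtropical,4085,978
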