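key	group	n	carriers
ATM:c.652C>T	healthy	710	0
CHEK2:c.593-1G>T	healthy	710	0
FANCD2:c.2494+2T>C	healthy	710	0
FANCI:c.206del	healthy	710	0
RAD51C:c.890_899del	healthy	710	0
CEP57:c.791C>G	healthy	710	0
RECQL4:c.2636del	healthy	710	0
ATM:c.995A>G	healthy	710	0
ATM:c.1595G>A	healthy	710	2
ATM:c.5750G>A	healthy	710	2
ATM:c.8560C>T	healthy	710	0
BRIP1:c.847T>C	healthy	710	0
CHEK2:c.349A>G	healthy	710	.
CHEK2:c.695G>T	healthy	710	0
MSH2:c.1571G>A	healthy	710	.
MSH6:c.1729C>T	healthy	710	.
TP53:c.839G>A	healthy	710	0
ATM:c.652C>T	cancer_panel	504	1
CHEK2:c.593-1G>T	cancer_panel	504	1
FANCD2:c.2494+2T>C	cancer_panel	504	1
FANCI:c.206del	cancer_panel	504	0
RAD51C:c.890_899del	cancer_panel	504	2
CEP57:c.791C>G	cancer_panel	504	0
RECQL4:c.2636del	cancer_panel	504	0
ATM:c.995A>G	cancer_panel	504	0
ATM:c.1595G>A	cancer_panel	504	6
ATM:c.5750G>A	cancer_panel	504	3
ATM:c.8560C>T	cancer_panel	504	0
BRIP1:c.847T>C	cancer_panel	504	1
CHEK2:c.349A>G	cancer_panel	504	.
CHEK2:c.695G>T	cancer_panel	504	1
MSH2:c.1571G>A	cancer_panel	504	.
MSH6:c.1729C>T	cancer_panel	504	.
TP53:c.839G>A	cancer_panel	504	0
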