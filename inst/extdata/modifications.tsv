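# Modification registry: monoisotopic mass deltas used in probe-site
# searches. 'formula' is the elemental composition where it is known;
# probe-remnant deltas without a derivable composition are opaque constants.
# targets: residue letters the modification may sit on (comma-separated).
name	delta_mass	targets	kind	formula
vs_remnant	192.0569	C	variable	NA
vme_remnant	172.0848	C	variable	NA
pa_remnant	112.0637	C	variable	NA
vps_dadps_remnant	387.1940	C	variable	NA
vps_dde_remnant	344.1631	C	variable	NA
vpe_hydrolyzed_remnant	158.0691	C	variable	NA
carbamidomethyl	57.0215	C	fixed	C2H3NO
oxidation	15.9949	M	variable	O
gg_remnant	114.0429	K	variable	C4H6N2O2
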