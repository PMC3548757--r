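# Nearest-neighbor duplex parameters, DNA/DNA, 1 M NaCl reference state.
# Watson-Crick steps: unified oligonucleotide parameters (SantaLucia 1998).
# Single internal mismatches: Allawi & SantaLucia 1997-1998, Peyret et al. 1999
# (includes the tandem G.T entries GG/TT, GT/TG, TG/GT from the same series).
# Step notation XY/WZ: top strand 5'-XY-3' paired antiparallel with bottom
# strand 3'-WZ-5' (X pairs W, Y pairs Z). Strand-symmetric presentations are
# resolved at load time.
# Units: dH in J/mol, dS in J/(K*mol) (converted from kcal/cal, 1 cal = 4.184 J).
# Salt correction: delta-G += -477.0 * (n_pairs - 1) * ln([Na+]) J/mol per
# helix (entropic form of the unified [Na+] adjustment, -0.114 kcal/mol per
# phosphate pair); zero at the 1 M reference concentration.
step	dH	dS	class
AA/TT	-33053.6	-92.8848	match
AT/TA	-30124.8	-85.3536	match
CA/GT	-35564	-94.9768	match
CG/GC	-44350.4	-113.805	match
CT/GA	-32635.2	-87.864	match
GA/CT	-34308.8	-92.8848	match
GC/CG	-41003.2	-102.09	match
GG/CC	-33472	-83.2616	match
GT/CA	-35145.6	-93.7216	match
TA/AT	-30124.8	-89.1192	match
AA/TA	5020.8	7.1128	mismatch
AA/TC	9623.2	19.2464	mismatch
AA/TG	-2510.4	-9.6232	mismatch
AC/TA	22175.2	61.0864	mismatch
AC/TC	0	-18.4096	mismatch
AC/TT	2928.8	0.8368	mismatch
AG/TA	-2928.8	-9.6232	mismatch
AG/TG	-12970.4	-39.748	mismatch
AG/TT	4184	3.7656	mismatch
AT/TC	-5020.8	-25.9408	mismatch
AT/TG	-10460	-34.7272	mismatch
AT/TT	-11296.8	-45.1872	mismatch
CA/GA	-3765.6	-17.5728	mismatch
CA/GC	7949.6	15.4808	mismatch
CA/GG	-2928.8	-9.6232	mismatch
CC/GA	2510.4	-2.5104	mismatch
CC/GC	-6276	-30.1248	mismatch
CC/GT	-3347.2	-18.828	mismatch
CG/GA	-16736	-55.2288	mismatch
CG/GG	-20501.6	-64.0152	mismatch
CG/GT	-17154.4	-48.9528	mismatch
CT/GC	-6276	-25.5224	mismatch
CT/GG	-11715.2	-33.472	mismatch
CT/GT	-20920	-66.1072	mismatch
GA/CA	-12133.6	-41.0032	mismatch
GA/CC	21756.8	59.4128	mismatch
GA/CG	-2510.4	-4.184	mismatch
GC/CA	-2928.8	-15.8992	mismatch
GC/CC	15062.4	37.2376	mismatch
GC/CT	9623.2	22.5936	mismatch
GG/CA	2092	13.3888	mismatch
GG/CG	-25104	-66.1072	mismatch
GG/CT	13807.2	43.5136	mismatch
GG/TT	24267.2	68.1992	mismatch
GT/CC	21756.8	56.484	mismatch
GT/CG	-18409.6	-51.4632	mismatch
GT/CT	-9204.8	-35.1456	mismatch
GT/TG	17154.4	39.748	mismatch
TA/AA	19664.8	53.9736	mismatch
TA/AC	14225.6	33.472	mismatch
TA/AG	2928.8	2.9288	mismatch
TC/AA	31798.4	84.5168	mismatch
TC/AC	25522.4	68.6176	mismatch
TC/AT	5020.8	2.9288	mismatch
TG/AA	12552	30.9616	mismatch
TG/AG	6694.4	15.0624	mismatch
TG/AT	-418.4	-7.1128	mismatch
TG/GT	-5857.6	-25.9408	mismatch
TT/AC	4184	2.9288	mismatch
TT/AG	-5439.2	-22.1752	mismatch
TT/AT	836.8	-6.276	mismatch
init_A/T	9623.2	17.1544	initiation
init_G/C	418.4	-11.7152	initiation
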