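cell_class	channel	ecc_deg	freq_hz	gain
parasol	achromatic	5	1	0.6
parasol	achromatic	5	2	0.9
parasol	achromatic	5	4	1.3
parasol	achromatic	5	8	1.9
parasol	achromatic	5	16	2.4
parasol	achromatic	5	32	1.9
parasol	achromatic	5	64	0.5
parasol	achromatic	25	1	0.7
parasol	achromatic	25	2	1.1
parasol	achromatic	25	4	1.7
parasol	achromatic	25	8	2.6
parasol	achromatic	25	16	3.4
parasol	achromatic	25	32	2.9
parasol	achromatic	25	64	0.9
parasol	achromatic	40	1	0.8
parasol	achromatic	40	2	1.2
parasol	achromatic	40	4	1.9
parasol	achromatic	40	8	3
parasol	achromatic	40	16	4
parasol	achromatic	40	32	3.9
parasol	achromatic	40	64	1.2
midget	achromatic	5	1	0.15
midget	achromatic	5	2	0.2
midget	achromatic	5	4	0.28
midget	achromatic	5	8	0.35
midget	achromatic	5	16	0.38
midget	achromatic	5	32	0.25
midget	achromatic	5	64	0.06
midget	achromatic	25	1	0.2
midget	achromatic	25	2	0.27
midget	achromatic	25	4	0.36
midget	achromatic	25	8	0.46
midget	achromatic	25	16	0.5
midget	achromatic	25	32	0.36
midget	achromatic	25	64	0.09
midget	achromatic	40	1	0.22
midget	achromatic	40	2	0.3
midget	achromatic	40	4	0.4
midget	achromatic	40	8	0.52
midget	achromatic	40	16	0.58
midget	achromatic	40	32	0.44
midget	achromatic	40	64	0.11
midget	chromatic	5	1	0.55
midget	chromatic	5	2	0.6
midget	chromatic	5	4	0.62
midget	chromatic	5	8	0.55
midget	chromatic	5	16	0.35
midget	chromatic	5	32	0.12
midget	chromatic	5	64	0.02
midget	chromatic	25	1	0.5
midget	chromatic	25	2	0.55
midget	chromatic	25	4	0.57
midget	chromatic	25	8	0.5
midget	chromatic	25	16	0.32
midget	chromatic	25	32	0.1
midget	chromatic	25	64	0.02
midget	chromatic	40	1	0.45
midget	chromatic	40	2	0.5
midget	chromatic	40	4	0.52
midget	chromatic	40	8	0.45
midget	chromatic	40	16	0.28
midget	chromatic	40	32	0.09
midget	chromatic	40	64	0.015
bistratified	chromatic	5	1	0.35
bistratified	chromatic	5	2	0.4
bistratified	chromatic	5	4	0.45
bistratified	chromatic	5	8	0.42
bistratified	chromatic	5	16	0.28
bistratified	chromatic	5	32	0.1
bistratified	chromatic	5	64	0.02
bistratified	chromatic	25	1	0.38
bistratified	chromatic	25	2	0.44
bistratified	chromatic	25	4	0.5
bistratified	chromatic	25	8	0.47
bistratified	chromatic	25	16	0.32
bistratified	chromatic	25	32	0.12
bistratified	chromatic	25	64	0.025
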