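hypothesis	OGA	PGA	3pct	4pct	10x	3.2-4.1x	ABGD	PAB_BI	PAB_ML	PRD_BI	PRD_ML	GSI_BI	GSI_ML	GMYC
A	+	+	+	+	-	+	+	+	-	+	-	+	+	+
B	na	na	na	na	na	na	na	na	na	na	na	na	na	na
C	+	+	+	+	+	+	+	+	+	+	+	+	+	+
D	-	-	-	-	-	-		na	+	na	-	-	+	-
Da	+	+	+	+	+	+	+	-	-	+	+	+	+	+
Db	+	+	-	+	-	+	+	-	-	-	-	+	+	+
E	-	-	-	-	-	-		+	+	-	-	-	-	
Ea	-	-	-	-	-	-	-					-	-	-
Eb	+	+	-	-	-	-	+	-	-	+	-	+	+	-
Ea3-4	+	+	+	+	+	+	+	-	-	+	+	+	+	+
Eb1-4	+	+	+	+	+	+	-	-	-	+	+	+	+	+
Eb5-8	+	+	+	+	-	+	-	-	-	+	+	+	+	+
F	-	-	-	+	-	-	-					-	-	-
F+Ea1-2	+	+	+	+	+	+	+	+	+	+	+	+	+	+
S	+	+	-	+	-	+		+	+	-	-	+	+	-
Sa	+	+	+	+	+	+	+	-	-	+	+	+	+	+
Sb	+	+	+	+	+	+	+	-	-	+	+	+	+	+
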