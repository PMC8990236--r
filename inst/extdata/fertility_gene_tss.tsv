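gene	strand	five_prime_pos	peak_start	peak_stop	utr_length_published
AR	-	84957236	84958298	84958477	1241
IGF1	-	66203733	66203715	66204034	301
INHA	+	107614722	107614985	107614491	231
PENK	-	23423774	23424308	23424459	685
RPS20	-	23140852	23141036	23141219	367
RTKN2	-	17967072	17966877	17967512	440
SERPINA7	+	53237946	53236117	53236027	1919
SOX9	-	60169843	60169524	60170244	401
STAT3	-	43676141	43676023	43676320	179
STK11IP	+	107634090	107634194	107633817	273
TAF1	-	80923837	80923816	80923981	144
TAF9B	+	74070058	74070080	74069977	81
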