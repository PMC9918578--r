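@UTF8
@Begin
@Languages:	eng
@Participants:	MOT Mother, FAT Father, CHI Target_Child
@ID:	eng|synthetic|MOT|30;|female|||Mother|||
@ID:	eng|synthetic|FAT|32;|male|||Father|||
@ID:	eng|synthetic|CHI|2;0.|female|||Target_Child|||
@Comment:	synthetic transcript written for package examples; not CHILDES data
*MOT:	look at the doggie .
*CHI:	doggie !
*MOT:	yes a big doggie
	and a little kitty too .
%mor:	dependent tier ignored by the reader
*FAT:	do you want some milk ?
*CHI:	milk milk !
*MOT:	here is your milk in the blue cup .
*FAT:	&um say thank_you to mommy .
@End
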